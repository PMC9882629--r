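#' Direction of enrichment
#'
#' The sign of the median member Wald statistic: positive medians are
#' `"+"`, negative `"-"`; an exactly zero median is reported `"+"`
#' with a tie flag.
#'
#' @param wald_by_gene named numeric vector of per-gene Wald
#'   statistics.
#' @param members member gene ids.
#' @return list `direction` (`"+"`/`"-"`), `median_wald`, `tie`.
#' @export
direction_of_enrichment <- function(wald_by_gene, members) {
  vals <- wald_by_gene[intersect(members, names(wald_by_gene))]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stopf("no member statistics present")
  med <- median(vals)
  list(direction = if (med < 0) "-" else "+", median_wald = med,
       tie = med == 0)
}

#' Gene-set enrichment of per-gene Wald statistics
#'
#' Default method `"ranktest"` is a two-sided competitive rank test of
#' member vs non-member statistics (Wilcoxon rank-sum with normal
#' approximation and tie correction). Method `"gsea"` is conventional
#' preranked running-sum enrichment with gene-permutation p-values
#' (seeded, >= `nperm` permutations). Either way the direction of
#' each set is assigned by the median-member-Wald rule and
#' Benjamini-Hochberg FDR is computed across the sets tested within
#' this contrast. Sets with fewer than `min_size` members present
#' among the tested genes are skipped and listed in attribute
#' `skipped`.
#'
#' @param wald_by_gene named per-gene Wald statistics (one contrast).
#' @param sets a [gene_set_collection()].
#' @param method `"ranktest"` or `"gsea"`.
#' @param min_size minimum member genes present.
#' @param nperm permutations for `"gsea"`.
#' @param seed seed for the permutation method.
#' @return data.frame of class `enrichment_table`: `set_id`, `family`,
#'   `n_present`, `stat`, `p`, `fdr`, `direction`, `median_wald`,
#'   `tie`.
#' @export
enrich_contrast <- function(wald_by_gene, sets, method = c("ranktest", "gsea"),
                            min_size = 5, nperm = 10000, seed = 1L) {
  method <- match.arg(method)
  stats_v <- wald_by_gene[is.finite(wald_by_gene)]
  if (!length(stats_v)) stopf("no finite statistics supplied")
  present <- lapply(sets$sets, function(m) intersect(m, names(stats_v)))
  n_present <- lengths(present)
  skipped <- names(sets$sets)[n_present < min_size]
  keep <- names(sets$sets)[n_present >= min_size]
  if (!length(keep)) {
    out <- data.frame(set_id = character(0), family = character(0),
                      n_present = integer(0), stat = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      direction = character(0), median_wald = numeric(0),
                      tie = logical(0))
    attr(out, "skipped") <- skipped
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }

  if (method == "gsea") {
    set.seed(seed)
    fg <- fgsea::fgseaSimple(pathways = sets$sets[keep], stats = stats_v,
                             nperm = nperm, minSize = min_size,
                             maxSize = length(stats_v), nproc = 0)
    fg <- as.data.frame(fg)
    stat <- setNames(fg$ES, fg$pathway)[keep]
    pval <- setNames(fg$pval, fg$pathway)[keep]
  } else {
    stat <- pval <- setNames(numeric(length(keep)), keep)
    for (id in keep) {
      memb <- stats_v[present[[id]]]
      bg <- stats_v[setdiff(names(stats_v), present[[id]])]
      wt <- wilcox.test(memb, bg, alternative = "two.sided",
                        exact = FALSE, correct = TRUE)
      stat[id] <- unname(wt$statistic)
      pval[id] <- wt$p.value
    }
  }
  dir_info <- lapply(keep, function(id)
    direction_of_enrichment(stats_v, present[[id]]))
  out <- data.frame(
    set_id = keep,
    family = unname(sets$families[keep]),
    n_present = unname(n_present[keep]),
    stat = unname(stat),
    p = unname(pval),
    fdr = p.adjust(unname(pval), method = "BH"),
    direction = vapply(dir_info, `[[`, "", "direction"),
    median_wald = vapply(dir_info, `[[`, 0, "median_wald"),
    tie = vapply(dir_info, `[[`, TRUE, "tie"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  attr(out, "method") <- method
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Member statistics of one set
#'
#' Returns the Wald statistics of a set's member genes that are
#' present in the data (for density displays), in stable gene-id
#' order, plus the list of members absent from the data.
#'
#' @param wald_by_gene named per-gene statistics.
#' @param sets a [gene_set_collection()].
#' @param set_id set identifier.
#' @return list `stats` (named numeric), `dropped` (absent members).
#' @export
member_stat_distribution <- function(wald_by_gene, sets, set_id) {
  if (!set_id %in% names(sets$sets)) stopf("unknown set id '%s'", set_id)
  members <- sort(sets$sets[[set_id]])
  present <- members[members %in% names(wald_by_gene)]
  if (!length(present))
    warnf("no members of %s present in the data", set_id)
  list(stats = wald_by_gene[present], dropped = setdiff(members, present))
}

#' Family-level time-course summary
#'
#' For each family, timepoint and direction: 100 x (number of that
#' family's sets significantly enriched with that direction) / (total
#' sets of the family in the collection).
#'
#' @param tables named list of `enrichment_table`s keyed by timepoint
#'   (or contrast label).
#' @param sets the [gene_set_collection()] the tables were computed
#'   against.
#' @param alpha FDR threshold for significance.
#' @return data.frame of class `family_summary`: `family`,
#'   `timepoint`, `direction`, `n_enriched`, `n_family`, `percent`.
#' @export
family_summary <- function(tables, sets, alpha = 0.05) {
  fam_sizes <- table(sets$families)
  out <- list()
  for (tp in names(tables)) {
    tab <- tables[[tp]]
    if (nrow(tab) && !all(tab$set_id %in% names(sets$sets)))
      stopf("table '%s' contains sets outside the collection", tp)
    for (fam in names(fam_sizes)) {
      for (dir in c("+", "-")) {
        n_enr <- sum(tab$family == fam & tab$fdr < alpha &
                       tab$direction == dir, na.rm = TRUE)
        out[[length(out) + 1]] <- data.frame(
          family = fam, timepoint = tp, direction = dir,
          n_enriched = n_enr, n_family = as.integer(fam_sizes[[fam]]),
          percent = 100 * n_enr / fam_sizes[[fam]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("family_summary", "data.frame")
  out
}
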