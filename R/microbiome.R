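# Microbiome composition summaries and change-outcome association.
#
# All functions consume long-format taxa tibbles (see read_taxa_table()):
# relative abundances are compositional within each phylogenetic level.

#' Shannon diversity of a composition
#'
#' Shannon diversity index in natural-log units (nats): -sum p_i ln p_i,
#' with the 0 ln 0 = 0 convention for absent taxa.
#'
#' @param p numeric vector of relative abundances (non-negative, summing to
#'   1 within tolerance)
#' @return diversity in nats
#' @export
shannon_diversity <- function(p) {
  if (any(p < 0)) rlang::abort("negative abundance")
  if (abs(sum(p) - 1) > 1e-6) {
    rlang::warn("abundances do not sum to 1; renormalizing")
    p <- p / sum(p)
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Firmicutes/Bacteroidetes ratio of a sample
#'
#' Ratio of summed relative abundances of taxa whose phylum lineage is
#' Firmicutes to those whose lineage is Bacteroidetes. No pseudocount is
#' applied: a sample without Bacteroidetes has an undefined ratio and
#' returns `NA` with a warning.
#'
#' @param sample long taxa tibble for one sample with `phylum` and
#'   `abundance` columns
#' @return unitless ratio, or `NA` when the Bacteroidetes sum is zero
#' @export
fb_ratio <- function(sample) {
  assert_cols(sample, c("phylum", "abundance"), "taxa sample")
  if (all(is.na(sample$phylum))) rlang::abort("missing phylum lineage tags")
  f <- sum(sample$abundance[sample$phylum == "Firmicutes"], na.rm = TRUE)
  b <- sum(sample$abundance[sample$phylum == "Bacteroidetes"], na.rm = TRUE)
  if (b == 0) {
    rlang::warn("Bacteroidetes aggregate is zero; ratio undefined")
    return(NA_real_)
  }
  f / b
}

#' Default propionate-producer taxon set
#'
#' A configurable, literature-derived default list of genera commonly
#' treated as propionate producers (succinate- and propanediol-pathway
#' fermenters). The membership of this functional group is a package
#' convention, not a published list, and should be overridden when a study
#' defines its own set.
#'
#' @return character vector of genus names
#' @export
propionate_producers <- function() {
  c("Akkermansia", "Bacteroides", "Prevotella", "Veillonella",
    "Phascolarctobacterium", "Dialister", "Roseburia")
}

#' Summed relative abundance of a functional taxon group
#'
#' @param sample long taxa tibble for one sample with `taxon` and
#'   `abundance`
#' @param taxa character vector naming the member taxa (non-empty)
#' @return summed relative abundance of the members present in the sample
#' @export
functional_aggregate <- function(sample, taxa = propionate_producers()) {
  if (length(taxa) == 0L) rlang::abort("empty taxon set")
  assert_cols(sample, c("taxon", "abundance"), "taxa sample")
  sum(sample$abundance[sample$taxon %in% taxa])
}

#' Associations between taxa changes and clinical changes
#'
#' Pearson correlation between each taxon's change in relative abundance
#' (end minus start) and each clinical outcome's change, across
#' participants, with Benjamini-Hochberg adjustment applied within each
#' phylogenetic level across all of that level's (taxon, outcome) pairs
#' (`per_outcome = TRUE` restricts the adjustment families to one outcome at
#' a time). Pairs with a zero-variance vector carry no information and are
#' skipped with a warning. Changes are raw abundance differences; no
#' log-ratio transform is applied.
#'
#' @param delta_taxa tibble with `participant_id`, `taxon`, `level`,
#'   `delta` (change in relative abundance per participant)
#' @param delta_outcomes tibble with `participant_id` and one numeric column
#'   per clinical change
#' @param fdr_q significance threshold on the BH-adjusted q-value
#'   (default 0.15)
#' @param per_outcome adjust within (level, outcome) families instead of
#'   whole levels
#' @return tibble with `level`, `taxon`, `outcome`, `r`, `p_value`,
#'   `q_value`, `n`, `significant`
#' @export
change_outcome_associations <- function(delta_taxa, delta_outcomes,
                                        fdr_q = 0.15, per_outcome = FALSE) {
  assert_cols(delta_taxa, c("participant_id", "taxon", "level", "delta"),
              "taxa changes")
  outcomes <- setdiff(names(delta_outcomes)[vapply(delta_outcomes, is.numeric,
                                                   logical(1))],
                      "participant_id")
  n_skipped <- 0L
  rows <- list()
  for (key in unique(paste(delta_taxa$level, delta_taxa$taxon, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- delta_taxa[delta_taxa$level == parts[1] & delta_taxa$taxon == parts[2], ]
    for (oc in outcomes) {
      merged <- dplyr::inner_join(sub, delta_outcomes[, c("participant_id", oc)],
                                  by = "participant_id")
      merged <- merged[!is.na(merged$delta) & !is.na(merged[[oc]]), ]
      if (nrow(merged) < 4L) next
      if (stats::sd(merged$delta) == 0 || stats::sd(merged[[oc]]) == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      ct <- stats::cor.test(merged$delta, merged[[oc]], method = "pearson")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level = parts[1], taxon = parts[2], outcome = oc,
        r = unname(ct$estimate), p_value = ct$p.value, n = nrow(merged)
      )
    }
  }
  if (n_skipped > 0L) {
    rlang::warn(sprintf("%d zero-variance (taxon, outcome) pair(s) skipped", n_skipped))
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(level = character(), taxon = character(),
                          outcome = character(), r = numeric(),
                          p_value = numeric(), q_value = numeric(),
                          n = integer(), significant = logical()))
  }
  res <- dplyr::bind_rows(rows)
  family <- if (per_outcome) paste(res$level, res$outcome, sep = "\r") else res$level
  res$q_value <- NA_real_
  for (f in unique(family)) {
    idx <- family == f
    res$q_value[idx] <- stats::p.adjust(res$p_value[idx], method = "BH")
  }
  res$significant <- res$q_value <= fdr_q
  res
}

#' Per-participant taxa changes between two timepoints
#'
#' Convenience reshape from a bundle-style taxa table (with
#' `participant_id` and `timepoint` columns) to the change table consumed by
#' [change_outcome_associations()]. Taxa absent from a sample count as zero
#' abundance at that timepoint.
#'
#' @param taxa long taxa tibble with `participant_id`, `timepoint`,
#'   `taxon`, `level`, `abundance`
#' @param from,to timepoint labels (defaults `"baseline"`, `"T6"`)
#' @return tibble with `participant_id`, `taxon`, `level`, `delta`
#' @export
taxa_changes <- function(taxa, from = "baseline", to = "T6") {
  assert_cols(taxa, c("participant_id", "timepoint", "taxon", "level",
                      "abundance"), "taxa table")
  taxa[taxa$timepoint %in% c(from, to), ] |>
    tidyr::pivot_wider(id_cols = c("participant_id", "taxon", "level"),
                       names_from = "timepoint", values_from = "abundance",
                       values_fill = 0) |>
    dplyr::mutate(delta = .data[[to]] - .data[[from]]) |>
    dplyr::select("participant_id", "taxon", "level", "delta")
}

#' Baseline diversity against a clinical outcome
#'
#' Sorts participants by the outcome, smooths their Shannon diversities with
#' a centered rolling mean of `window` participants (the curve a
#' sorted-participant diversity overlay draws), and reports the Pearson
#' correlation between raw diversity and the outcome. With fewer
#' participants than the window the curve is absent but the correlation is
#' still computed when n >= 3; a constant diversity vector has no defined
#' correlation and is reported as `NA`.
#'
#' @param diversity numeric vector of per-participant Shannon diversities
#' @param outcome numeric vector of the clinical outcome, same order
#' @param window rolling-average window in participants (default 5)
#' @return list with `correlation`, `p_value`, and `curve` (tibble of
#'   `outcome`, `diversity`, `rolling_mean`, sorted by outcome; `NULL` when
#'   n < window)
#' @export
diversity_vs_outcome <- function(diversity, outcome, window = 5) {
  stopifnot(length(diversity) == length(outcome))
  ok <- !is.na(diversity) & !is.na(outcome)
  diversity <- diversity[ok]; outcome <- outcome[ok]
  n <- length(diversity)
  correlation <- NA_real_; p_value <- NA_real_
  if (n >= 3L && stats::sd(diversity) > 0 && stats::sd(outcome) > 0) {
    ct <- stats::cor.test(diversity, outcome)
    correlation <- unname(ct$estimate); p_value <- ct$p.value
  }
  curve <- NULL
  if (n >= window) {
    ord <- order(outcome)
    d <- diversity[ord]
    roll <- stats::filter(d, rep(1 / window, window), sides = 2)
    curve <- tibble::tibble(outcome = outcome[ord], diversity = d,
                            rolling_mean = as.numeric(roll))
  }
  list(correlation = correlation, p_value = p_value, curve = curve)
}
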