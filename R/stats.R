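# Capture-efficiency, recovery, blood-cell depletion, viability and
# cytometry-gating statistics.

#' Per-class partition fractions across output streams
#'
#' For each size class, converts per-replicate counts in the three output
#' streams to percentages; means and sample SDs are taken across
#' replicates. The three stream fractions sum to 100% for every class.
#'
#' @param counts Tidy count table with columns `replicate`, `size_class`,
#'   `stage1_product`, `stage2_product`, `waste` (e.g. from
#'   [make_count_table()] or [simulate_device()] counts).
#' @return Tibble: `size_class`, `stream`, `mean_pct`, `sd_pct`,
#'   `n_replicates`. Classes with zero total in a replicate are flagged
#'   by `NaN` fractions with a warning.
#' @examples
#' ct <- make_count_table(list(large_cluster = c(.918, .075, .007)),
#'                        300, 5, seed = 1)
#' partition_fractions(ct)
#' @export
partition_fractions <- function(counts) {
  stopifnot(all(c("replicate", "size_class", "stage1_product",
                  "stage2_product", "waste") %in% names(counts)))
  long <- counts |>
    tidyr::pivot_longer(cols = c("stage1_product", "stage2_product",
                                 "waste"),
                        names_to = "stream", values_to = "n") |>
    dplyr::group_by(.data$replicate, .data$size_class) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  if (any(!is.finite(long$pct))) {
    warning("some class/replicate totals are zero; their fractions are ",
            "undefined", call. = FALSE)
  }
  long |>
    dplyr::group_by(.data$size_class, .data$stream) |>
    dplyr::summarize(mean_pct = mean(.data$pct),
                     sd_pct = stats::sd(.data$pct),
                     n_replicates = dplyr::n(), .groups = "drop")
}

#' Total recovery into the product streams
#'
#' Recovery is the Stage 1 plus Stage 2 product fraction (equivalently
#' 100% minus the waste fraction). The SD of the sum is computed per
#' replicate (recovery is computed within each replicate, then
#' summarized), which is exact rather than an independence approximation.
#'
#' @param counts As for [partition_fractions()].
#' @return Tibble: `size_class`, `recovery_pct`, `sd_pct`,
#'   `n_replicates`.
#' @examples
#' ct <- make_count_table(list(large_cluster = c(.918, .075, .007)),
#'                        300, 5, seed = 1)
#' total_recovery(ct)
#' @export
total_recovery <- function(counts) {
  counts |>
    dplyr::group_by(.data$replicate, .data$size_class) |>
    dplyr::summarize(
      rec = 100 * sum(.data$stage1_product + .data$stage2_product) /
        sum(.data$stage1_product + .data$stage2_product + .data$waste),
      .groups = "drop") |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarize(recovery_pct = mean(.data$rec),
                     sd_pct = stats::sd(.data$rec),
                     n_replicates = dplyr::n(), .groups = "drop")
}

#' Sum stream fractions reported as mean +/- SD
#'
#' Worked-example arithmetic on published per-stream fractions: the
#' recovery is the sum of the two product-stream means; its SD, when
#' requested, combines the replicate SDs under the independence
#' approximation `sqrt(sd1^2 + sd2^2)` (the underlying replicate-level
#' correlation is not recoverable from printed summaries, which is why
#' [total_recovery()] on raw counts is preferred).
#'
#' @param mean_pcts Numeric vector of stream mean percentages to sum.
#' @param sd_pcts Optional vector of their SDs.
#' @return Tibble with `recovery_pct` and (if SDs given) `sd_pct`.
#' @examples
#' combine_fractions(c(91.8, 7.5))  # 99.3
#' @export
combine_fractions <- function(mean_pcts, sd_pcts = NULL) {
  out <- tibble::tibble(recovery_pct = sum(mean_pcts))
  if (!is.null(sd_pcts)) out$sd_pct <- sqrt(sum(sd_pcts^2))
  out
}

#' Log10 depletion of a contaminating cell type
#'
#' `D = log10(input / output)` on total counts (concentration times
#' volume). A zero output count is reported as a censored bound
#' (`> log10(input)`) rather than infinity, reflecting the counting
#' chamber's detection floor.
#'
#' @param input_count,output_count Total cells in and out (> 0 input).
#' @return Tibble: `log10_depletion`, `censored`.
#' @examples
#' log10_depletion(1e6, 10)   # 5
#' @export
log10_depletion <- function(input_count, output_count) {
  stopifnot(all(input_count > 0), all(output_count >= 0))
  cens <- output_count == 0
  d <- ifelse(cens, log10(input_count),
              log10(input_count / output_count))
  tibble::tibble(log10_depletion = d, censored = cens)
}

#' Viability record
#'
#' @param live,total Live and total cell counts; at least 200 cells must
#'   be counted per condition.
#' @param condition Label (e.g. flow rate and stream).
#' @return One-row tibble with `viability_pct`.
#' @export
viability_record <- function(live, total, condition = NA_character_) {
  if (any(total < 200)) {
    stop("fewer than 200 cells counted; viability requires >= 200 per ",
         "condition", call. = FALSE)
  }
  stopifnot(all(live >= 0), all(live <= total))
  tibble::tibble(condition = condition, live = live, total = total,
                 viability_pct = 100 * live / total)
}

#' Compare viability between a treated condition and control
#'
#' Pooled-variance two-sample t test on replicate viability percentages,
#' two-sided, with a 95% confidence interval on the difference; the
#' significance flag is `p < alpha`. Viability experiments run in
#' duplicate or triplicate; with so few replicates the pooled test keeps
#' sensible degrees of freedom where per-group variance estimates are
#' too unstable to weight separately.
#'
#' @param treated,control Numeric vectors of replicate viability
#'   percentages (each from >= 200-cell counts), or tibbles from
#'   [viability_record()].
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `estimate` (treated minus control, percentage
#'   points), `conf_low`, `conf_high`, `p_value`, `significant`.
#' @export
viability_compare <- function(treated, control, alpha = 0.05) {
  pv <- function(x) {
    if (is.data.frame(x)) x$viability_pct else x
  }
  tr <- pv(treated)
  ct <- pv(control)
  stopifnot(length(tr) >= 2 || length(ct) >= 2)
  ht <- stats::t.test(tr, ct, var.equal = TRUE, conf.level = 1 - alpha)
  tibble::tibble(estimate = unname(diff(rev(ht$estimate))),
                 conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
                 p_value = ht$p.value,
                 significant = ht$p.value < alpha)
}

#' Gate an imaging-cytometry event
#'
#' Gate order: a nuclear stain is required (otherwise the event is
#' excluded as debris/anuclear); epithelial-positive, leukocyte-negative
#' events are cancer cells, viable when viability-positive and
#' apoptosis-negative and nonviable otherwise; leukocyte-positive events
#' are leukocytes; anything else is excluded.
#'
#' @param events Tibble with intensity columns `nuclear`, `viability`,
#'   `apoptosis`, `epithelial`, `leukocyte`.
#' @param thresholds Named positivity thresholds for the same channels.
#' @return `events` with a `gate` column: one of `excluded`,
#'   `viable_cancer`, `nonviable_cancer`, `leukocyte`.
#' @export
cytometry_classify <- function(events,
                               thresholds = c(nuclear = 1,
                                              viability = 1,
                                              apoptosis = 1,
                                              epithelial = 1,
                                              leukocyte = 1)) {
  need <- c("nuclear", "viability", "apoptosis", "epithelial",
            "leukocyte")
  stopifnot(all(need %in% names(events)), all(need %in%
                                                names(thresholds)))
  pos <- function(ch) events[[ch]] >= thresholds[[ch]]
  gate <- dplyr::case_when(
    !pos("nuclear") ~ "excluded",
    pos("epithelial") & !pos("leukocyte") &
      pos("viability") & !pos("apoptosis") ~ "viable_cancer",
    pos("epithelial") & !pos("leukocyte") ~ "nonviable_cancer",
    pos("leukocyte") ~ "leukocyte",
    TRUE ~ "excluded")
  dplyr::mutate(events, gate = gate)
}

#' White-blood-cell counts from paired nuclear/reporter frame counts
#'
#' Leukocyte counts follow from subtracting reporter-positive (cancer)
#' nuclei from total nuclei in paired frames of the nuclear and reporter
#' channels.
#'
#' @param nuclear_counts,reporter_counts Paired per-frame counts.
#' @return Tibble with per-frame `wbc` and totals as attributes.
#' @export
wbc_counts <- function(nuclear_counts, reporter_counts) {
  stopifnot(length(nuclear_counts) == length(reporter_counts),
            all(nuclear_counts >= reporter_counts))
  tibble::tibble(frame = seq_along(nuclear_counts),
                 nuclei = nuclear_counts, cancer = reporter_counts,
                 wbc = nuclear_counts - reporter_counts)
}
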