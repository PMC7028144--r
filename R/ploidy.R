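# Ploidy-class quantification from DNA-content fluorescence intensities:
# 2C anchor estimation, deterministic log2-bin classification, per-sample
# class proportions and genotype contrasts.

ploidy_classes <- function() c("2C", "4C", "8C", "16C", "32C")

#' Estimate the 2C peak intensity of a nuclei sample
#'
#' Searches for modes of a kernel density estimate of `log2(intensity)` and
#' returns the intensity of the lowest mode whose density exceeds 10% of the
#' global density maximum. This replaces interactive gating with a
#' reproducible anchor for [classify_ploidy()]; supply the anchor explicitly
#' when the 2C population is too scarce to form a qualifying mode.
#'
#' @param intensities Positive fluorescence intensities (>= 100 nuclei).
#' @return The estimated 2C peak intensity.
#' @export
estimate_ploidy_anchor <- function(intensities) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 100L) {
    stop_rootkin("at least 100 nuclei are required to estimate the 2C anchor",
                 "rootkin_error_insufficient_data")
  }
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop_rootkin("intensities must be positive and finite", "rootkin_error_domain")
  }
  d <- stats::density(log2(intensities), n = 2048)
  y <- d$y
  k <- length(y)
  is_mode <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k], FALSE)
  qualifying <- which(is_mode & y > 0.10 * max(y))
  if (length(qualifying) == 0) {
    stop_rootkin("no density mode exceeds 10% of the maximum: cannot estimate the 2C anchor",
                 "rootkin_error_estimation")
  }
  2^d$x[qualifying[1]]
}

#' Classify nuclei into ploidy classes
#'
#' Deterministic log2 binning around the 2C anchor: a nucleus with intensity
#' `I` gets class index `round(log2(I / anchor))`, clipped to the 2C-32C
#' range. Classification is invariant to rescaling intensities and anchor by
#' a common factor.
#'
#' @param intensities Positive fluorescence intensities.
#' @param anchor 2C peak intensity (> 0), e.g. from
#'   [estimate_ploidy_anchor()].
#' @return A factor with levels `2C, 4C, 8C, 16C, 32C`, one per nucleus.
#' @export
classify_ploidy <- function(intensities, anchor) {
  intensities <- as.numeric(intensities)
  if (!is.numeric(anchor) || length(anchor) != 1L || anchor <= 0) {
    stop_rootkin("`anchor` must be a positive scalar", "rootkin_error_parameter")
  }
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop_rootkin("intensities must be positive and finite", "rootkin_error_domain")
  }
  k <- pmin(pmax(round(log2(intensities / anchor)), 0), 4)
  factor(ploidy_classes()[k + 1], levels = ploidy_classes())
}

#' Per-sample ploidy class counts and proportions
#'
#' @param nuclei A data frame with columns `sample_id`, `genotype` and either
#'   `class` (a factor from [classify_ploidy()]) or `intensity` plus an
#'   `anchor` argument.
#' @param anchor Optional 2C anchor; when supplied (or estimated with
#'   `estimate_anchor = TRUE`) intensities are classified first.
#' @param estimate_anchor Estimate the anchor per sample with
#'   [estimate_ploidy_anchor()] when none is given.
#' @param min_intensity,max_intensity Optional gates applied before
#'   classification (debris/doublet exclusion for real data).
#' @return A tibble with one row per sample: per-class counts `n_2C` ...
#'   `n_32C`, proportions `p_2C` ... `p_32C`, total `n` and `anchor` used.
#'   Proportions sum to 1.
#' @export
ploidy_proportions <- function(nuclei, anchor = NULL, estimate_anchor = FALSE,
                               min_intensity = NULL, max_intensity = NULL) {
  if (!"sample_id" %in% names(nuclei)) {
    stop_rootkin("`nuclei` must contain `sample_id`", "rootkin_error_schema")
  }
  if (!"genotype" %in% names(nuclei)) nuclei$genotype <- NA_character_
  nuclei %>%
    dplyr::group_by(.data$sample_id, .data$genotype) %>%
    dplyr::group_modify(function(df, key) {
      if (!"class" %in% names(df)) {
        ints <- df$intensity
        if (!is.null(min_intensity)) ints <- ints[ints >= min_intensity]
        if (!is.null(max_intensity)) ints <- ints[ints <= max_intensity]
        a <- anchor
        if (is.null(a)) {
          if (!estimate_anchor) {
            stop_rootkin("supply `anchor` or set `estimate_anchor = TRUE`",
                         "rootkin_error_parameter")
          }
          a <- estimate_ploidy_anchor(ints)
        }
        cls <- classify_ploidy(ints, a)
      } else {
        cls <- factor(df$class, levels = ploidy_classes())
        a <- if (is.null(anchor)) NA_real_ else anchor
      }
      if (length(cls) < 1L) {
        stop_rootkin("no nuclei left after gating", "rootkin_error_insufficient_data")
      }
      counts <- table(cls)
      props <- as.numeric(counts) / sum(counts)
      out <- tibble::tibble(n = sum(counts), anchor = a)
      for (i in seq_along(ploidy_classes())) {
        out[[paste0("n_", ploidy_classes()[i])]] <- as.integer(counts[i])
      }
      for (i in seq_along(ploidy_classes())) {
        out[[paste0("p_", ploidy_classes()[i])]] <- props[i]
      }
      out
    }) %>%
    dplyr::ungroup()
}

#' Contrast ploidy-class proportions between two genotypes
#'
#' Welch two-sample t-test per ploidy class on the per-sample proportions.
#' Raw p-values are reported, as is usual for these figure-level contrasts;
#' an optional Benjamini-Hochberg column across the five classes can be
#' added.
#'
#' @param proportions Output of [ploidy_proportions()] containing exactly two
#'   genotypes with at least two samples each.
#' @param adjust Add a `p_bh` Benjamini-Hochberg column (default `FALSE`).
#' @return A tibble with one row per class: group means, Welch `t`, `df`,
#'   `p`, and optionally `p_bh`.
#' @export
compare_ploidy <- function(proportions, adjust = FALSE) {
  genotypes <- unique(proportions$genotype)
  if (length(genotypes) != 2L) {
    stop_rootkin("`proportions` must contain exactly two genotypes",
                 "rootkin_error_parameter")
  }
  a <- dplyr::filter(proportions, .data$genotype == genotypes[1])
  b <- dplyr::filter(proportions, .data$genotype == genotypes[2])
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop_rootkin("each genotype needs at least two samples", "rootkin_error_parameter")
  }
  rows <- purrr::map(ploidy_classes(), function(cl) {
    col <- paste0("p_", cl)
    wa <- a[[col]]
    wb <- b[[col]]
    ht <- welch_t(wa, wb)
    tibble::tibble(
      class = cl,
      mean_a = mean(wa), mean_b = mean(wb),
      t = ht$statistic, df = ht$df, p = ht$p_value
    )
  })
  out <- dplyr::bind_rows(rows)
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  attr(out, "genotypes") <- genotypes
  out
}
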