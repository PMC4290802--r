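# Utility metric and risk-utility sweeps comparing the three release
# mechanisms across privacy budgets.

#' True top-K SNPs by allelic chi-square
#'
#' The reference set against which private releases are judged: the `k`
#' SNPs with the largest allelic chi-square statistics, ties broken by
#' ascending panel position.
#'
#' @inheritParams score_chi2
#' @param k Number of SNPs.
#' @return A tibble with columns `rank`, `snp_id`, `chi2`.
#' @examples
#' panel <- simulate_panel(20, 100, 100, n_assoc = 3, effect = 0.3, seed = 5)
#' true_top_k(panel, 3)
#' @export
true_top_k <- function(panel, k) {
  check_panel(panel)
  if (k < 1 || k > nrow(panel)) {
    stop("`k` must be between 1 and nrow(panel).", call. = FALSE)
  }
  scored <- score_chi2(panel)
  ord <- order(-scored$chi2, seq_len(nrow(scored)))[seq_len(k)]
  tibble::tibble(rank = seq_len(k),
                 snp_id = scored$snp_id[ord],
                 chi2 = scored$chi2[ord])
}

#' Utility of a private release
#'
#' The fraction of the true top-K recovered:
#' `u = |true intersect released| / K`. Both arguments may be character
#' vectors of SNP ids, `snp_release` objects, or tibbles with a `snp_id`
#' column.
#'
#' @param released,true_top The released and reference SNP sets (same
#'   size `K`).
#' @return A number in `[0, 1]`; 1 iff the sets are equal.
#' @examples
#' utility(c("a", "b", "c"), c("a", "c", "d"))  # 2/3
#' @export
utility <- function(released, true_top) {
  rel <- as_snp_ids(released)
  tru <- as_snp_ids(true_top)
  if (length(rel) != length(tru)) {
    stop("`released` and `true_top` must have the same size K.",
         call. = FALSE)
  }
  length(intersect(rel, tru)) / length(tru)
}

as_snp_ids <- function(x) {
  if (inherits(x, "snp_release")) return(x$selected$snp_id)
  if (is.data.frame(x)) {
    if (!"snp_id" %in% names(x)) {
      stop("Data frame must have a `snp_id` column.", call. = FALSE)
    }
    return(x$snp_id)
  }
  as.character(x)
}

#' Risk-utility sweep over privacy budgets, K, and thresholds
#'
#' Runs each requested mechanism `reps` times per grid cell
#' (epsilon x k x threshold p-value) on one fixed panel and reports the
#' mean and standard deviation of the utility against the true chi-square
#' top-K. The three mechanisms are the Laplace mechanism on the chi-square
#' score (`"laplace_chi2"`), the exponential mechanism on the chi-square
#' score (`"exponential_chi2"`), and the exponential mechanism on the
#' Hamming distance score (`"exponential_hamming"`, sensitivity 1). The
#' threshold p-values apply to the Hamming mechanism only; the chi-square
#' mechanisms are reported once per (epsilon, k) with `p_star = NA`.
#'
#' @inheritParams score_chi2
#' @param epsilons Positive privacy budgets to sweep.
#' @param ks Values of K to sweep.
#' @param p_stars Threshold p-values for the Hamming score. Default
#'   `c(0.1, 0.01) / nrow(panel)`.
#' @param mechanisms Subset of
#'   `c("laplace_chi2", "exponential_chi2", "exponential_hamming")`.
#' @param chi2_sens Sensitivity for the chi-square score mechanisms
#'   (required if any is requested; audit with [chi2_sensitivity()]).
#' @param reps Mechanism draws per grid cell (default 200).
#' @param seed Base seed; per-repetition seeds are derived from it.
#' @return A tibble of class `risk_utility_sweep` with columns `mechanism`,
#'   `epsilon`, `k`, `p_star`, `mean_utility`, `sd_utility`, `reps`,
#'   `seed`, sorted by mechanism, k, p_star, epsilon.
#' @seealso [autoplot.risk_utility_sweep()]
#' @examples
#' panel <- simulate_panel(30, 80, 80, n_assoc = 5, effect = 0.3, seed = 9)
#' risk_utility_sweep(panel, epsilons = c(1, 10), ks = 3,
#'                    mechanisms = "exponential_hamming", reps = 20,
#'                    seed = 1)
#' @export
risk_utility_sweep <- function(panel, epsilons, ks,
                               p_stars = c(0.1, 0.01) / nrow(panel),
                               mechanisms = c("laplace_chi2",
                                              "exponential_chi2",
                                              "exponential_hamming"),
                               chi2_sens = NULL, reps = 200, seed = 1L) {
  check_panel(panel)
  mechanisms <- match.arg(mechanisms, several.ok = TRUE)
  if (any(epsilons <= 0)) stop("All `epsilons` must be > 0.", call. = FALSE)
  if (reps < 1) stop("`reps` must be >= 1.", call. = FALSE)
  needs_chi2 <- any(mechanisms %in% c("laplace_chi2", "exponential_chi2"))
  if (needs_chi2 && is.null(chi2_sens)) {
    stop("`chi2_sens` is required for chi-square-score mechanisms; ",
         "audit a value with chi2_sensitivity().", call. = FALSE)
  }

  scored_chi2 <- score_chi2(panel)
  hamming_scored <- if ("exponential_hamming" %in% mechanisms) {
    stats::setNames(
      lapply(p_stars, function(p) score_hamming(panel, p)),
      as.character(p_stars)
    )
  }

  grid <- dplyr::bind_rows(
    if (needs_chi2) tidyr::expand_grid(
      mechanism = intersect(mechanisms,
                            c("laplace_chi2", "exponential_chi2")),
      k = ks, p_star = NA_real_, epsilon = epsilons),
    if ("exponential_hamming" %in% mechanisms) tidyr::expand_grid(
      mechanism = "exponential_hamming",
      k = ks, p_star = p_stars, epsilon = epsilons)
  )

  run_cell <- function(mechanism, k, p_star, epsilon, cell) {
    truth <- true_top_k(panel, k)$snp_id
    us <- vapply(seq_len(reps), function(rep) {
      rs <- cell_seed(seed, cell, rep)
      rel <- switch(
        mechanism,
        laplace_chi2 = release_laplace(scored_chi2, "chi2", k, epsilon,
                                       chi2_sens, seed = rs),
        exponential_chi2 = release_exponential(scored_chi2, "chi2", k,
                                               epsilon, chi2_sens,
                                               seed = rs),
        exponential_hamming = release_exponential(
          hamming_scored[[as.character(p_star)]], "hamming", k,
          epsilon, 1, seed = rs)
      )
      utility(rel, truth)
    }, numeric(1))
    tibble::tibble(mean_utility = mean(us),
                   sd_utility = stats::sd(us))
  }

  res <- dplyr::bind_cols(
    grid,
    purrr::pmap_dfr(
      c(grid, list(cell = seq_len(nrow(grid)))),
      run_cell
    ),
    tibble::tibble(reps = reps, seed = as.integer(seed))
  )
  res <- dplyr::arrange(res, .data$mechanism, .data$k, .data$p_star,
                        .data$epsilon)
  class(res) <- c("risk_utility_sweep", class(res))
  res
}

# Derived per-(cell, repetition) seed, kept inside 32-bit integer range.
cell_seed <- function(seed, cell, rep) {
  as.integer((as.numeric(seed) + 7919 * cell + 104729 * rep) %% 2147483647)
}

#' Plot a risk-utility sweep
#'
#' Mean utility against the privacy budget epsilon (log scale), one line
#' per mechanism, faceted by K (rows) and threshold p-value (columns).
#'
#' @param object A [risk_utility_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_utility_sweep <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    p_lab = ifelse(is.na(.data$p_star), "all",
                   sprintf("p* = %.2g", .data$p_star))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$epsilon, .data$mean_utility,
                                   colour = .data$mechanism)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$k),
      cols = ggplot2::vars(.data$p_lab),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = expression(epsilon), y = "mean utility",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
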