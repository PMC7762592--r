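# Genome-length based capsid architecture prediction: each genome is
# assigned the T-number whose model-mean genome length is nearest (in linear
# kbp), over the deduplicated generalized T grid; architectures with
# T <= 4 are flagged as small-capsid candidates.

#' Assign a predicted capsid architecture to a genome length
#'
#' Evaluates the genome allometric model on the candidate T grid and assigns
#' the grid value whose model-mean genome length is nearest to the observed
#' length. Distance is measured in linear kbp by default ("nearest average
#' genome length" taken literally); ties at the midpoint between two
#' consecutive means go to the smaller T (parsimony).
#'
#' @param length_bp Genome length(s) in base pairs (positive; vectorized).
#' @param fit Genome-model `"allometric_fit"` (e.g.
#'   `printed_params()$genome_kbp`).
#' @param series Candidate T grid, a sorted numeric vector from [t_grid()]
#'   (default: all four lattices, deduplicated, `T < 40`).
#' @param log_space If `TRUE`, match in log10-kbp instead of linear kbp
#'   (sensitivity analysis; default `FALSE`).
#' @return Data frame with one row per genome: `length_bp`, `assigned_t`,
#'   `nearest_mean_kbp`, `abs_distance_kbp`, `continuous_t`,
#'   `is_small_candidate` (`assigned_t <= 4`).
#' @examples
#' g <- from_printed_params(0.37, 1.47, "genome_kbp")
#' assign_t(11600, g)$assigned_t  # 3
#' @export
assign_t <- function(length_bp, fit, series = t_grid(40), log_space = FALSE) {
  stopifnot(inherits(fit, "allometric_fit"))
  if (length(series) == 0) stop("empty candidate T series")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("genome lengths must be positive")
  }
  series <- sort(series)
  means <- predict_mean(fit, series)
  kbp <- length_bp / 1000
  pick <- vapply(kbp, function(g) {
    d <- if (log_space) abs(log10(g) - log10(means)) else abs(g - means)
    which.min(d)  # first minimum = smaller t on ties
  }, integer(1))
  data.frame(
    length_bp = as.integer(round(length_bp)),
    assigned_t = series[pick],
    nearest_mean_kbp = means[pick],
    abs_distance_kbp = abs(kbp - means[pick]),
    continuous_t = inverse_t(fit, kbp),
    is_small_candidate = series[pick] <= 4 + 1e-9,
    stringsAsFactors = FALSE
  )
}

#' Classify a batch of genomes and tabulate predicted architectures
#'
#' @param records Data frame of genome records with columns `id`,
#'   `length_bp` (and optionally `source`), e.g. from [read_fasta_lengths()],
#'   [read_length_table()] or [gen_genome_mixture()].
#' @inheritParams assign_t
#' @return List of class `"t_classification"` with `assignments` (one row
#'   per genome) and `frequency` (counts and percentages per assigned T).
#' @export
classify_batch <- function(records, fit, series = t_grid(40),
                           log_space = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("id", "length_bp") %in% names(records)))
  asg <- assign_t(records$length_bp, fit, series, log_space)
  asg <- cbind(data.frame(id = records$id, stringsAsFactors = FALSE), asg)
  if ("source" %in% names(records)) {
    asg$source <- records$source
    asg <- asg[, c("id", "source", setdiff(names(asg), c("id", "source")))]
  }
  tab <- table(factor(signif(asg$assigned_t, 10)))
  freq <- data.frame(
    t = as.numeric(names(tab)),
    count = as.integer(tab),
    percent = 100 * as.integer(tab) / nrow(asg),
    stringsAsFactors = FALSE
  )
  structure(list(assignments = asg, frequency = freq),
            class = "t_classification")
}

#' @export
print.t_classification <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf("Predicted capsid architectures for %d genomes\n", n))
  cat(sprintf("  T range %.4g - %.4g; median T = %.4g; %d small candidates (T <= 4)\n",
              min(x$assignments$assigned_t), max(x$assignments$assigned_t),
              stats::median(x$assignments$assigned_t),
              sum(x$assignments$is_small_candidate)))
  invisible(x)
}

#' Gaussian kernel density estimate of genome lengths
#'
#' Probability density of genome lengths (kbp) using Gaussian kernels with
#' the rule-of-thumb default bandwidth `0.9 * min(sd, IQR/1.34) * n^(-1/5)`
#' (the `bw.nrd0` default of [stats::density()]), evaluated on 512 evenly
#' spaced grid points spanning the data extended by three bandwidths.
#'
#' @inheritParams classify_batch
#' @param bandwidth Optional bandwidth in kbp (default: rule of thumb).
#' @return List of class `"genome_density"` with `grid` (kbp), `density`,
#'   `bandwidth` (kbp), `n`, and `peaks` (see [find_peaks()]).
#' @export
estimate_density <- function(records, bandwidth = NULL) {
  stopifnot(is.data.frame(records), "length_bp" %in% names(records))
  x <- records$length_bp / 1000
  if (length(unique(x)) < 2) {
    stop("need at least 2 distinct genome lengths for a density estimate")
  }
  d <- stats::density(x, bw = if (is.null(bandwidth)) "nrd0" else bandwidth,
                      kernel = "gaussian", n = 512, cut = 3)
  est <- structure(list(grid = d$x, density = d$y, bandwidth = d$bw,
                        n = length(x)),
                   class = "genome_density")
  est$peaks <- find_peaks(est)
  est
}

#' Peaks of a genome-length density estimate
#'
#' Strict interior local maxima of the estimated density, sorted by density
#' in decreasing order (the first row is the dominant peak).
#'
#' @param est A `"genome_density"` from [estimate_density()], or any list
#'   with `grid` and `density`.
#' @return Data frame with `location_kbp` and `density`, ordered by
#'   decreasing density.
#' @export
find_peaks <- function(est) {
  y <- est$density
  n <- length(y)
  if (n < 3) return(data.frame(location_kbp = numeric(0), density = numeric(0)))
  i <- 2:(n - 1)
  is_peak <- y[i] > y[i - 1] & y[i] > y[i + 1]
  idx <- i[is_peak]
  out <- data.frame(location_kbp = est$grid[idx], density = y[idx])
  out[order(-out$density), , drop = FALSE]
}

#' @export
print.genome_density <- function(x, ...) {
  cat(sprintf("Genome-length density: n = %d, bandwidth = %.3g kbp, %d peak(s)\n",
              x$n, x$bandwidth, nrow(x$peaks)))
  if (nrow(x$peaks)) {
    cat("  peaks (kbp):",
        paste(sprintf("%.1f", utils::head(x$peaks$location_kbp, 5)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Small-capsid candidate report
#'
#' Filters the classified genomes to those with assigned architecture at or
#' below a T-number threshold, sorted by assigned T then genome length, with
#' counts per architecture.
#'
#' @param classification A `"t_classification"` from [classify_batch()], or
#'   its `assignments` data frame.
#' @param threshold_t T-number cutoff (default 4, the small-capsid filter).
#' @return List of class `"candidate_report"` with `candidates`, `counts`
#'   and `threshold_t`.
#' @export
candidate_report <- function(classification, threshold_t = 4) {
  asg <- if (inherits(classification, "t_classification")) {
    classification$assignments
  } else classification
  stopifnot(is.data.frame(asg), "assigned_t" %in% names(asg))
  cand <- asg[asg$assigned_t <= threshold_t + 1e-9, , drop = FALSE]
  cand <- cand[order(cand$assigned_t, cand$length_bp), , drop = FALSE]
  rownames(cand) <- NULL
  counts <- if (nrow(cand)) {
    tab <- table(factor(signif(cand$assigned_t, 10)))
    data.frame(t = as.numeric(names(tab)), count = as.integer(tab))
  } else data.frame(t = numeric(0), count = integer(0))
  structure(list(candidates = cand, counts = counts,
                 threshold_t = threshold_t),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("Small-capsid candidates (T <= %.3g): %d genome(s)\n",
              x$threshold_t, nrow(x$candidates)))
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}
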