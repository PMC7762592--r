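# Structural metrics derived from a capsid measurement table: one row per
# cryo-EM capsid with interior/exterior diameters (5-fold vertex to vertex,
# nm), sphericities, surfaces (nm^2), volumes (nm^3), genome length (kbp)
# and the architecture index T.

.capsid_cols <- c("emdb_id", "t", "d_int", "d_ext", "sphericity_int",
                  "sphericity_ext", "s_int", "s_ext", "v_int", "v_ext",
                  "genome")

.check_capsid_table <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.capsid_cols, names(records))
  if (length(missing)) {
    stop("capsid table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0) stop("capsid table is empty")
  with(records, {
    if (any(v_int <= 0) || any(v_ext <= 0)) stop("volumes must be positive")
    if (any(d_ext <= d_int)) stop("exterior diameter must exceed interior")
    if (any(s_ext <= s_int)) stop("exterior surface must exceed interior")
    if (any(genome <= 0)) stop("genome lengths must be positive")
  })
  invisible(records)
}

#' Derive structural metrics from capsid measurements
#'
#' Shell thickness is the difference of exterior and interior radii (input
#' diameters are halved); genome packing density divides the genome length
#' (converted at exactly 1000 bp/kbp) by the interior volume; per-protein
#' surface areas divide each surface by the major-capsid-protein count
#' `60 * T0` (optionally scaled by the surface fraction attributed to MCPs).
#'
#' @param records Capsid table (data frame with columns `emdb_id, t, d_int,
#'   d_ext, sphericity_int, sphericity_ext, s_int, s_ext, v_int, v_ext,
#'   genome`), e.g. from [gen_capsid_table()] or [read_capsid_csv()].
#' @param mcp_surface_fraction Fraction of the capsid surface assigned to
#'   major capsid proteins (default 1: all of it).
#' @return The input with added columns `thickness` (nm), `genome_density`
#'   (bp/nm^3), `mcp_area_int`, `mcp_area_ext` (nm^2) and
#'   `ext_int_surface_excess` (fraction, `s_ext/s_int - 1`).
#' @export
derive_metrics <- function(records, mcp_surface_fraction = 1) {
  .check_capsid_table(records)
  stopifnot(mcp_surface_fraction > 0, mcp_surface_fraction <= 1)
  # 60 * T0 major capsid proteins; recover T0 from the lattice area factor
  # and require it to be an achievable classic T-number (h^2 + hk + k^2)
  classic <- function(n) {
    for (h in 0:ceiling(sqrt(n))) for (k in 0:h) {
      if (h == 0 && k == 0) next
      if (h * h + h * k + k * k == n) return(TRUE)
    }
    FALSE
  }
  mcp <- vapply(records$t, function(tt) {
    for (af in .area_factors) {
      t0c <- tt / af
      if (abs(t0c - round(t0c)) < 1e-4 && round(t0c) >= 1 &&
          classic(round(t0c))) {
        return(60 * round(t0c))
      }
    }
    stop(sprintf("T = %g is not in the generalized T-number series", tt))
  }, numeric(1))
  records$thickness <- (records$d_ext - records$d_int) / 2
  records$genome_density <- records$genome * 1000 / records$v_int
  records$mcp_area_int <- records$s_int * mcp_surface_fraction / mcp
  records$mcp_area_ext <- records$s_ext * mcp_surface_fraction / mcp
  records$ext_int_surface_excess <- records$s_ext / records$s_int - 1
  records
}

#' Summarize a capsid structure table
#'
#' Min-max ranges and means for each measured and derived property, in the
#' units of the input table (nm, nm^2, nm^3, kbp, bp/nm^3).
#'
#' @inheritParams derive_metrics
#' @return A data frame with one row per property (`n`, `min`, `mean`,
#'   `max`), preceded by the capsid count.
#' @export
summarize_table <- function(records) {
  recs <- derive_metrics(records)
  props <- c("t", "d_int", "d_ext", "sphericity_int", "sphericity_ext",
             "s_int", "s_ext", "v_int", "v_ext", "genome", "thickness",
             "genome_density", "mcp_area_int", "mcp_area_ext",
             "ext_int_surface_excess")
  out <- data.frame(
    property = c("capsids_analyzed", props),
    n = nrow(recs),
    min = c(NA, vapply(props, function(p) min(recs[[p]]), numeric(1))),
    mean = c(NA, vapply(props, function(p) mean(recs[[p]]), numeric(1))),
    max = c(NA, vapply(props, function(p) max(recs[[p]]), numeric(1))),
    stringsAsFactors = FALSE
  )
  out$min[1] <- out$mean[1] <- out$max[1] <- nrow(recs)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of a capsid variable with capsid diameter
#'
#' Non-parametric (Spearman rank) correlation with a two-tailed test, as used
#' to screen which structural properties track capsid size.
#'
#' @inheritParams derive_metrics
#' @param variable Name of a measured or derived column to correlate.
#' @param diameter Which diameter to correlate against: `"d_ext"` (default)
#'   or `"d_int"`.
#' @return List of class `"correlation_report"` with `variable`, `rho`,
#'   `p_value`, `n`.
#' @export
correlate_with_diameter <- function(records, variable,
                                    diameter = c("d_ext", "d_int")) {
  diameter <- match.arg(diameter)
  recs <- derive_metrics(records)
  if (nrow(recs) < 4) stop("need at least 4 records for a correlation test")
  if (!variable %in% names(recs)) stop("unknown variable: ", variable)
  v <- recs[[variable]]
  if (stats::sd(v) == 0) {
    stop("variable '", variable, "' is constant; correlation is undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(v, recs[[diameter]], method = "spearman",
                    alternative = "two.sided")
  )
  structure(list(variable = variable, rho = unname(ct$estimate),
                 p_value = ct$p.value, n = nrow(recs)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Spearman correlation with capsid diameter: %s\n", x$variable))
  cat(sprintf("  rho = %.3f, two-tailed p = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric sample (3 <= n <= 5000, non-constant).
#' @return List with `statistic` (W) and `p_value`.
#' @export
test_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("constant sample: normality test undefined")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Read / write a capsid structure table as CSV
#'
#' The CSV header must contain the columns `emdb_id, t, d_int, d_ext,
#' sphericity_int, sphericity_ext, s_int, s_ext, v_int, v_ext, genome`
#' (diameters in nm, surfaces in nm^2, volumes in nm^3, genome in kbp).
#'
#' @param path CSV path.
#' @return A validated capsid table data frame.
#' @export
read_capsid_csv <- function(path) {
  recs <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_capsid_table(recs)
  recs
}

#' @rdname read_capsid_csv
#' @param records Capsid table to write.
#' @export
write_capsid_csv <- function(records, path) {
  .check_capsid_table(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
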