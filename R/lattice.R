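# Area factors of the four Archimedean icosahedral lattices relative to the
# hexagonal lattice at equal T0.  The rhombitrihexagonal factor is the exact
# tiling area ratio (1 hexagon + 2 triangles + 3 squares per unit cell over
# the hexagon alone), 4/3 + 2*sqrt(3)/3.
.tiling_labels <- c("hexagonal", "trihexagonal", "snub_hexagonal",
                    "rhombitrihexagonal")

.area_factors <- c(
  hexagonal          = 1,
  trihexagonal       = 4 / 3,
  snub_hexagonal     = 7 / 3,
  rhombitrihexagonal = 4 / 3 + 2 * sqrt(3) / 3
)

#' Archimedean lattice classes for icosahedral capsids
#'
#' An icosahedral capsid can organize its proteins in one of four plane
#' lattices: hexagonal, trihexagonal, snub hexagonal, and rhombitrihexagonal.
#' Each lattice multiplies the classic triangulation number by a fixed area
#' factor \eqn{\alpha_i}: 1, 4/3, 7/3 and \eqn{4/3 + 2\sqrt{3}/3 \approx 2.488}
#' respectively. Major capsid proteins occupy the hexagonal positions; the
#' secondary polygons (triangles and squares) of the non-hexagonal lattices
#' hold minor capsid proteins. The snub hexagonal lattice is chiral.
#'
#' @param label One of `"hexagonal"`, `"trihexagonal"`, `"snub_hexagonal"`,
#'   `"rhombitrihexagonal"`. Short forms `"hex"`, `"tri"`/`"trihex"`,
#'   `"snub"`, `"rhombi"` are accepted.
#' @param chirality `"laevo"`, `"dextro"` or `"none"`; only meaningful for the
#'   snub hexagonal lattice (defaults to `"laevo"` there, `"none"` elsewhere).
#'
#' @return An object of class `"tiling_class"`: a list with elements `label`,
#'   `area_factor` and `chirality`.
#' @examples
#' tiling_class("trihexagonal")$area_factor  # 4/3
#' @export
tiling_class <- function(label, chirality = NULL) {
  if (inherits(label, "tiling_class")) return(label)
  stopifnot(is.character(label), length(label) == 1L)
  aliases <- c(hex = "hexagonal", h = "hexagonal",
               tri = "trihexagonal", trihex = "trihexagonal",
               t = "trihexagonal",
               snub = "snub_hexagonal", s = "snub_hexagonal",
               rhombi = "rhombitrihexagonal", r = "rhombitrihexagonal")
  if (label %in% names(aliases)) label <- aliases[[label]]
  label <- match.arg(label, .tiling_labels)
  if (is.null(chirality)) {
    chirality <- if (label == "snub_hexagonal") "laevo" else "none"
  }
  chirality <- match.arg(chirality, c("laevo", "dextro", "none"))
  if (label != "snub_hexagonal" && chirality != "none") {
    stop("chirality is only meaningful for the snub hexagonal lattice")
  }
  if (label == "snub_hexagonal" && chirality == "none") chirality <- "laevo"
  structure(list(label = label, area_factor = .area_factors[[label]],
                 chirality = chirality),
            class = "tiling_class")
}

#' Classic triangulation number
#'
#' Computes the Caspar-Klug triangulation number
#' \eqn{T_0(h,k) = h^2 + hk + k^2} from the two non-negative lattice steps
#' joining consecutive 5-fold vertices of an icosahedral capsid.
#'
#' @param h,k Non-negative integer lattice steps, not both zero.
#' @return A positive integer; symmetric in `h` and `k`.
#' @examples
#' t0_number(2, 1)  # 7
#' @export
t0_number <- function(h, k) {
  if (length(h) != 1L || length(k) != 1L ||
      !is.finite(h) || !is.finite(k) ||
      h != round(h) || k != round(k)) {
    stop("h and k must be single finite integers")
  }
  if (h < 0 || k < 0) stop("lattice steps h and k must be non-negative")
  if (h == 0 && k == 0) stop("(h, k) = (0, 0) does not define a capsid")
  as.integer(h * h + h * k + k * k)
}

#' Generalized capsid architecture
#'
#' Constructs a capsid architecture from lattice steps `(h, k)` and a lattice
#' class. The generalized T-number is \eqn{T_i(h,k) = \alpha_i T_0(h,k)},
#' where \eqn{\alpha_i} is the lattice area factor; the number of major capsid
#' proteins is \eqn{60\,T_0} regardless of the lattice. `(h, k)` is reported
#' canonically with `h >= k` (the two orientations are mirror images).
#'
#' @inheritParams t0_number
#' @param tiling A [tiling_class()] or its label.
#' @return An object of class `"capsid_architecture"`: list with `h`, `k`,
#'   `tiling`, `t0`, `t`, `mcp_count` (major capsid proteins, `60 * t0`) and
#'   `total_protein_factor` (area-proportional total subunit count, `60 * t`).
#' @examples
#' generalized_t(1, 1, "hexagonal")$t        # 3
#' generalized_t(1, 0, "trihexagonal")$t     # 4/3
#' @export
generalized_t <- function(h, k, tiling = "hexagonal") {
  t0 <- t0_number(h, k)
  tiling <- tiling_class(tiling)
  if (h < k) { tmp <- h; h <- k; k <- tmp }
  structure(list(
    h = as.integer(h), k = as.integer(k), tiling = tiling,
    t0 = t0, t = tiling$area_factor * t0,
    mcp_count = 60L * t0,
    total_protein_factor = 60 * tiling$area_factor * t0
  ), class = "capsid_architecture")
}

#' Major capsid protein count
#'
#' @param arch A [generalized_t()] architecture.
#' @return `60 * t0`, the number of major capsid proteins in the shell.
#' @examples
#' mcp_count(generalized_t(3, 3, "hexagonal"))  # T = 27, 1620 proteins
#' @export
mcp_count <- function(arch) {
  stopifnot(inherits(arch, "capsid_architecture"))
  arch$mcp_count
}

#' @export
print.capsid_architecture <- function(x, ...) {
  cat(sprintf("Capsid architecture (h,k) = (%d,%d), %s lattice%s\n",
              x$h, x$k, x$tiling$label,
              if (x$tiling$label == "snub_hexagonal")
                paste0(" (", x$tiling$chirality, ")") else ""))
  cat(sprintf("  T0 = %d, T = %.6g, major capsid proteins = %d\n",
              x$t0, x$t, x$mcp_count))
  invisible(x)
}

#' Enumerate the generalized T-number series
#'
#' Lists every capsid architecture with generalized T-number `t <= t_max`
#' across all four Archimedean lattices, sorted by increasing `t`. Numerically
#' equal T values arising from different `(h, k, lattice)` combinations are
#' retained as distinct entries (e.g. T = 4 from hexagonal (2,0) and
#' trihexagonal (1,1)); within equal `t` the order is hexagonal <
#' trihexagonal < snub hexagonal < rhombitrihexagonal.
#'
#' @param t_max Upper bound on the generalized T-number (`>= 1`).
#' @return A list of `"capsid_architecture"` objects, ascending in `t`, with
#'   class `"architecture_series"`.
#' @examples
#' sapply(enumerate_architectures(3), `[[`, "t")  # 1, 4/3, 7/3, 2.488, 3
#' @export
enumerate_architectures <- function(t_max) {
  stopifnot(is.numeric(t_max), length(t_max) == 1L, is.finite(t_max))
  if (t_max < 1) stop("t_max must be at least 1 (no architecture has T < 1)")
  hk_max <- ceiling(sqrt(t_max))
  out <- list()
  for (h in 0:hk_max) {
    for (k in 0:h) {
      if (h == 0 && k == 0) next
      t0 <- h * h + h * k + k * k
      for (lab in .tiling_labels) {
        t <- .area_factors[[lab]] * t0
        if (t <= t_max + 1e-9) out[[length(out) + 1L]] <- generalized_t(h, k, lab)
      }
    }
  }
  ts <- vapply(out, `[[`, numeric(1), "t")
  rank <- match(vapply(out, function(a) a$tiling$label, character(1)),
                .tiling_labels)
  out <- out[order(ts, rank,
                   vapply(out, `[[`, integer(1), "h"),
                   vapply(out, `[[`, integer(1), "k"))]
  structure(out, class = c("architecture_series", "list"))
}

#' @export
print.architecture_series <- function(x, ...) {
  cat(sprintf("Generalized T-number series: %d architectures, T in [%.4g, %.4g]\n",
              length(x), x[[1]]$t, x[[length(x)]]$t))
  print(utils::head(architecture_table(x), 10L))
  if (length(x) > 10L) cat(sprintf("  ... and %d more\n", length(x) - 10L))
  invisible(x)
}

#' Architecture series as a data frame
#'
#' @param series A list of architectures from [enumerate_architectures()].
#' @return A data frame with columns `h`, `k`, `tiling`, `t0`, `t`,
#'   `mcp_count`.
#' @export
architecture_table <- function(series) {
  if (inherits(series, "capsid_architecture")) series <- list(series)
  data.frame(
    h = vapply(series, `[[`, integer(1), "h"),
    k = vapply(series, `[[`, integer(1), "k"),
    tiling = vapply(series, function(a) a$tiling$label, character(1)),
    t0 = vapply(series, `[[`, integer(1), "t0"),
    t = vapply(series, `[[`, numeric(1), "t"),
    mcp_count = vapply(series, `[[`, integer(1), "mcp_count"),
    stringsAsFactors = FALSE
  )
}

#' Write an architecture table to CSV
#'
#' @inheritParams architecture_table
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_architecture_csv <- function(series, path) {
  utils::write.csv(architecture_table(series), path, row.names = FALSE)
  invisible(path)
}

#' Deduplicated T-number grid
#'
#' The candidate grid used for genome-length classification: all generalized
#' T values below `t_max` across the four lattices, with numerically equal
#' values from different lattices collapsed to one grid point.
#'
#' @param t_max Upper bound (exclusive by default, matching the T < 40 grid
#'   used for classification); see `inclusive`.
#' @param inclusive If `TRUE`, keep `t == t_max`.
#' @return A sorted numeric vector of distinct T values.
#' @examples
#' head(t_grid(8))  # 1, 4/3, 7/3, 2.488..., 3, 16/3 ...
#' @export
t_grid <- function(t_max = 40, inclusive = FALSE) {
  series <- enumerate_architectures(t_max)
  ts <- vapply(series, `[[`, numeric(1), "t")
  if (!inclusive) ts <- ts[ts < t_max - 1e-9]
  ts <- sort(ts)
  # collapse numerically equal values (degenerate architectures)
  keep <- c(TRUE, diff(ts) > 1e-9)
  ts[keep]
}
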