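# Synthetic-data generators: a capsid measurement table with the scaling
# structure of real tailed-phage capsids (constant genome packing density,
# constant exterior surface per major capsid protein), and multimodal
# genome-length collections emulating isolate and gut-metagenome datasets.

#' Generate a synthetic capsid structure table
#'
#' Builds one record per capsid under the two conserved-quantity constraints
#' observed in real tailed phages: the exterior surface per major capsid
#' protein is drawn uniformly from `mcp_area_ext_range` (so the exterior
#' surface is `area * 60 * T`), and the genome packing density uniformly
#' from `density_range` (so the genome is `density * v_int`). Diameters come
#' from the quasi-spherical surface, the shell thickness grows with diameter
#' within 3-8 nm, and multiplicative lognormal noise of width
#' `noise_sd_log10` (base-10 log units) is applied to the diameters (one
#' shared factor, preserving interior < exterior) and to the genome.
#' By construction the noiseless table follows `G ~ T^1.5` and `D ~ T^0.5`.
#'
#' @param t_values Architecture indices (default the seven classic
#'   T-numbers of the structurally characterized capsids, 4-27).
#' @param replicates Records per T value, recycled; the default totals 23
#'   capsids with T = 7 oversampled, mirroring the composition of
#'   high-resolution capsid reconstructions.
#' @param density_range Genome packing density range, bp/nm^3.
#' @param mcp_area_ext_range Exterior surface per major capsid protein, nm^2.
#' @param noise_sd_log10 Lognormal noise width in log10 units (0 = exact
#'   scaling laws up to the uniform draws).
#' @param seed Optional integer seed; identical specs give identical tables.
#' @return A capsid table data frame (see [derive_metrics()] for columns).
#' @examples
#' tab <- gen_capsid_table(seed = 1)
#' nrow(tab)  # 23
#' @export
gen_capsid_table <- function(t_values = c(4, 7, 9, 12, 13, 16, 27),
                             replicates = c(3, 7, 3, 3, 3, 2, 2),
                             density_range = c(0.34, 0.62),
                             mcp_area_ext_range = c(24, 35),
                             noise_sd_log10 = 0.05,
                             seed = NULL) {
  stopifnot(all(t_values > 0), all(replicates >= 1),
            length(density_range) == 2, all(density_range > 0),
            diff(density_range) >= 0,
            length(mcp_area_ext_range) == 2, all(mcp_area_ext_range > 0),
            diff(mcp_area_ext_range) >= 0,
            noise_sd_log10 >= 0)
  if (!is.null(seed)) set.seed(seed)
  replicates <- rep_len(replicates, length(t_values))
  t <- rep(t_values, replicates)
  n <- length(t)
  a_ext <- runif(n, mcp_area_ext_range[1], mcp_area_ext_range[2])
  s_ext <- a_ext * 60 * t
  d_ext <- sqrt(s_ext / pi)
  # thickness grows with diameter, clamped to the observed 3-8 nm range;
  # the anchor diameters are the quasi-sphere values at the extreme T
  d_lo <- sqrt(mcp_area_ext_range[1] * 60 * min(t_values) / pi)
  d_hi <- sqrt(mcp_area_ext_range[2] * 60 * max(t_values) / pi)
  thick <- pmin(8, pmax(3, 3 + 5 * (d_ext - d_lo) / (d_hi - d_lo)))
  d_int <- d_ext - 2 * thick
  stopifnot(all(d_int > 0))
  v_int <- pi * d_int^3 / 6
  v_ext <- pi * d_ext^3 / 6
  s_int <- pi * d_int^2
  rho <- runif(n, density_range[1], density_range[2])
  genome <- rho * v_int / 1000  # kbp
  # capsids get more angular (lower sphericity) as they grow
  frac <- (d_ext - d_lo) / (d_hi - d_lo)
  sph_int <- pmin(0.75, pmax(0.25, 0.75 - 0.5 * frac + rnorm(n, 0, 0.02)))
  sph_ext <- pmin(0.55, pmax(0.14, 0.55 - 0.41 * frac + rnorm(n, 0, 0.02)))
  if (noise_sd_log10 > 0) {
    fd <- 10^rnorm(n, 0, noise_sd_log10)  # one factor for both diameters
    fg <- 10^rnorm(n, 0, noise_sd_log10)
    d_ext <- d_ext * fd; d_int <- d_int * fd
    s_ext <- s_ext * fd^2; s_int <- s_int * fd^2
    v_ext <- v_ext * fd^3; v_int <- v_int * fd^3
    genome <- genome * fg
  }
  data.frame(
    emdb_id = sprintf("SYN-%04d", seq_len(n)),
    t = t, d_int = d_int, d_ext = d_ext,
    sphericity_int = sph_int, sphericity_ext = sph_ext,
    s_int = s_int, s_ext = s_ext, v_int = v_int, v_ext = v_ext,
    genome = genome,
    stringsAsFactors = FALSE
  )
}

#' Genome-length mixture presets
#'
#' Lognormal mixture components anchored at the dominant peaks of the two
#' genome-length distributions the classifier is applied to: phage isolates
#' (peaks near 18.3, 42.0 and 158.9 kbp) and gut metagenome-assembled
#' phages (peaks near 12.6, 42.9, 98.2 and 160.8 kbp). Weights and spreads
#' are package choices; only the peak locations are anchored.
#'
#' @param preset `"isolates"` or `"gut"`.
#' @return Data frame with columns `mean_kbp`, `weight`, `sd_log10`.
#' @export
genome_mixture_preset <- function(preset = c("isolates", "gut")) {
  preset <- match.arg(preset)
  switch(preset,
    isolates = data.frame(
      mean_kbp = c(18.3, 42.0, 158.9),
      weight = c(0.15, 0.60, 0.25),
      sd_log10 = c(0.05, 0.05, 0.04)
    ),
    gut = data.frame(
      mean_kbp = c(12.6, 42.9, 98.2, 160.8),
      weight = c(0.10, 0.50, 0.20, 0.20),
      sd_log10 = c(0.05, 0.05, 0.04, 0.04)
    )
  )
}

#' Generate a synthetic genome-length collection
#'
#' Draws genome lengths from a lognormal mixture (genome lengths are
#' positive and right-skewed; each component has median `mean_kbp` and
#' base-10 log sd `sd_log10`), rounded to integer bp. Optionally writes a
#' multi-FASTA of random A/C/G/T sequences of the drawn lengths.
#'
#' @param components Mixture specification (data frame with `mean_kbp`,
#'   `weight`, `sd_log10`), e.g. from [genome_mixture_preset()]. Weights
#'   must sum to 1.
#' @param n Number of genomes.
#' @param seed Optional integer seed.
#' @param emit_fasta If `TRUE`, also write the sequences to `fasta_path`.
#' @param fasta_path FASTA output path (`.gz` for gzip) when `emit_fasta`.
#' @return Data frame of genome records: `id`, `length_bp`, `source`
#'   (`"synthetic"`), `component`.
#' @examples
#' g <- gen_genome_mixture(genome_mixture_preset("isolates"), n = 100, seed = 1)
#' range(g$length_bp)
#' @export
gen_genome_mixture <- function(components = genome_mixture_preset("isolates"),
                               n = 1000, seed = NULL, emit_fasta = FALSE,
                               fasta_path = NULL) {
  stopifnot(is.data.frame(components),
            all(c("mean_kbp", "weight", "sd_log10") %in% names(components)),
            all(components$mean_kbp > 0), all(components$weight > 0))
  if (abs(sum(components$weight) - 1) > 1e-6) {
    stop("mixture weights must sum to 1")
  }
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    stop("n must be a positive count")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$weight)
  kbp <- 10^(log10(components$mean_kbp[comp]) +
               rnorm(n, 0, components$sd_log10[comp]))
  records <- data.frame(
    id = sprintf("SYNG-%06d", seq_len(n)),
    length_bp = as.integer(pmax(1, round(kbp * 1000))),
    source = "synthetic",
    component = comp,
    stringsAsFactors = FALSE
  )
  if (emit_fasta) {
    if (is.null(fasta_path)) stop("fasta_path is required when emit_fasta")
    seqs <- Biostrings::DNAStringSet(vapply(records$length_bp, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)))
    names(seqs) <- records$id
    Biostrings::writeXStringSet(seqs, fasta_path,
                                compress = grepl("\\.gz$", fasta_path))
  }
  records
}
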