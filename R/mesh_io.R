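# Mesh writers: Wavefront OBJ, OFF, and Chimera BILD.  Output is plain text
# and byte-stable across runs (fixed %.9g formatting, no timestamps).

.fmt_coords <- function(v) paste(sprintf("%.9g", v), collapse = " ")

#' Write a cage mesh to OBJ, OFF or BILD
#'
#' @param mesh A [build_cage()] or [dual_mesh()] mesh.
#' @param format `"obj"` (Wavefront), `"off"` (Object File Format) or
#'   `"bild"` (Chimera BILD polygon primitives). Case-insensitive.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".off")
#' write_mesh(build_cage(generalized_t(1, 0, "hexagonal")), "off", f)
#' @export
write_mesh <- function(mesh, format = c("obj", "off", "bild"), path) {
  stopifnot(inherits(mesh, "cage_mesh"))
  if (!is.character(format) || length(format) != 1L ||
      !tolower(format) %in% c("obj", "off", "bild")) {
    stop("unknown mesh format; use one of \"obj\", \"off\", \"bild\"")
  }
  format <- tolower(format)
  V <- mesh$vertices
  lines <- switch(format,
    obj = c(
      sprintf("o cage_h%d_k%d_%s", mesh$architecture$h, mesh$architecture$k,
              mesh$architecture$tiling$label),
      vapply(seq_len(nrow(V)), function(i)
        paste("v", .fmt_coords(V[i, ])), character(1)),
      vapply(mesh$faces, function(fc)
        paste("f", paste(fc, collapse = " ")), character(1))
    ),
    off = c(
      "OFF",
      sprintf("%d %d %d", nrow(V), length(mesh$faces), nrow(mesh_edges(mesh))),
      vapply(seq_len(nrow(V)), function(i) .fmt_coords(V[i, ]), character(1)),
      vapply(mesh$faces, function(fc)
        paste(length(fc), paste(fc - 1L, collapse = " ")), character(1))
    ),
    bild = c(
      sprintf(".comment capsid cage (h,k)=(%d,%d) %s T=%.6g sphericity=%g",
              mesh$architecture$h, mesh$architecture$k,
              mesh$architecture$tiling$label, mesh$architecture$t,
              mesh$sphericity),
      ".color 0.65 0.7 0.85",
      vapply(mesh$faces, function(fc)
        paste(".polygon", .fmt_coords(t(V[fc, , drop = FALSE]))), character(1))
    )
  )
  writeLines(lines, path)
  invisible(path)
}

# minimal readers used for round-trip checks
.read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  stopifnot(identical(trimws(ln[1]), "OFF"))
  counts <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  V <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  faces <- lapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    x <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    x[-1] + 1L
  })
  list(V = V, faces = faces)
}

.read_obj <- function(path) {
  ln <- readLines(path)
  vlines <- grep("^v ", ln, value = TRUE)
  flines <- grep("^f ", ln, value = TRUE)
  V <- do.call(rbind, lapply(vlines, function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][-1])))
  faces <- lapply(flines, function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]][-1]))
  list(V = V, faces = faces)
}
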