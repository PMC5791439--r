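#' Read shape models from a delimited point table
#'
#' Expects a header row with columns `subject_id, surface, frame, ring, circ,
#' x, y, z` (tab- or comma-delimited; coordinates in mm, `ring`/`circ`
#' 0-based).  Subjects are returned in sorted-id order and validated against
#' a common grid dimension.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return List of [shape_model()] objects.
#' @export
read_points <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "surface", "frame", "ring", "circ", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("point table must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$subject_id, df$surface, df$frame, df$ring, df$circ)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1L] + 1L  # +1: header line
    stop("duplicate (subject, surface, frame, ring, circ) key at line ", dup)
  }
  R <- max(df$ring) + 1L; C <- max(df$circ) + 1L
  subjects <- sort(unique(df$subject_id))
  lapply(subjects, function(sid) {
    d <- df[df$subject_id == sid, ]
    grids <- list()
    for (fr in c("ED", "ES")) for (su in c("endo", "epi")) {
      g <- d[d$frame == fr & d$surface == su, ]
      if (nrow(g) != R * C) {
        have <- table(factor(g$ring, levels = 0:(R - 1L)))
        miss <- names(have)[have < C]
        stop(sprintf("subject %s %s/%s: expected %d points, got %d%s",
                     sid, su, fr, R * C, nrow(g),
                     if (length(miss)) paste0(" (incomplete ring(s) ",
                                              paste(miss, collapse = ", "), ")")
                     else ""))
      }
      g <- g[order(g$ring, g$circ), ]
      grids[[paste(fr, su)]] <-
        surface_grid(as.matrix(g[, c("x", "y", "z")]), R, C, su, fr)
    }
    shape_model(grids[["ED endo"]], grids[["ED epi"]],
                grids[["ES endo"]], grids[["ES epi"]], subject_id = sid)
  })
}

#' Write shape models to a delimited point table
#'
#' Inverse of [read_points()].  Coordinates are serialized with 6 significant
#' decimals (the documented roundtrip precision).
#'
#' @param models list of [shape_model()] objects.
#' @param path output file.
#' @param sep field separator.
#' @export
write_points <- function(models, path, sep = "\t") {
  rows <- lapply(models, function(m) {
    R <- m$R; C <- m$C
    ring <- rep(0:(R - 1L), each = C); circ <- rep(0:(C - 1L), times = R)
    do.call(rbind, lapply(
      list(c("ED", "endo", "ed_endo"), c("ED", "epi", "ed_epi"),
           c("ES", "endo", "es_endo"), c("ES", "epi", "es_epi")),
      function(w) data.frame(subject_id = as.character(m$subject_id),
                             surface = w[2], frame = w[1],
                             ring = ring, circ = circ,
                             x = signif(m[[w[3]]]$points[, 1], 7),
                             y = signif(m[[w[3]]]$points[, 2], 7),
                             z = signif(m[[w[3]]]$points[, 3], 7))))
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a closed surface mesh to ASCII PLY or OBJ
#'
#' @param x a [surface_grid()], [shape_model()] (all four surfaces exported
#'   to one file each with a suffix), or `triangle_mesh`.
#' @param path output path (for a `shape_model`, the suffixes
#'   `_{ed,es}_{endo,epi}` are inserted before the extension).
#' @param format `"ply"` or `"obj"`; default from the file extension.
#' @return Invisibly, the path(s) written.
#' @export
export_mesh <- function(x, path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    if (!ext %in% c("ply", "obj")) stop("unsupported mesh format: ", ext)
    format <- ext
  }
  if (inherits(x, "shape_model")) {
    stem <- sub("\\.[^.]+$", "", path)
    ext <- sub(".*\\.", "", path)
    out <- character(0)
    for (w in c("ed_endo", "ed_epi", "es_endo", "es_epi"))
      out <- c(out, export_mesh(x[[w]], sprintf("%s_%s.%s", stem, w, ext),
                                format))
    return(invisible(out))
  }
  mesh <- if (inherits(x, "surface_grid")) close_surface(x) else x
  if (!inherits(mesh, "triangle_mesh")) stop("cannot export this object")
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else {
    writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read an ASCII PLY or OBJ mesh written by [export_mesh()]
#'
#' @param path file path.
#' @return A `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  ln <- readLines(path)
  if (length(ln) && ln[1] == "ply") {
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", ln, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", ln, value = TRUE)))
    i0 <- which(ln == "end_header")
    v <- do.call(rbind, lapply(strsplit(ln[i0 + seq_len(nv)], " "),
                               function(s) as.numeric(s)))
    f <- do.call(rbind, lapply(strsplit(ln[i0 + nv + seq_len(nf)], " "),
                               function(s) as.integer(s[-1]) + 1L))
  } else {
    vl <- grep("^v ", ln, value = TRUE)
    fl <- grep("^f ", ln, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, " "),
                               function(s) as.numeric(s[-1])))
    f <- do.call(rbind, lapply(strsplit(fl, " "),
                               function(s) as.integer(s[-1])))
  }
  colnames(v) <- c("x", "y", "z")
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}
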