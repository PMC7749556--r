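#' Read and write diffusion-weighted volumes (NIfTI-1)
#'
#' Thin wrappers over RNifti preserving the voxel-to-world affine. A
#' gradient table in the FSL bval/bvec text dialect can be read alongside
#' the image; volume and gradient counts must agree.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param bval_path,bvec_path optional gradient table paths.
#' @return `read_dwi`: list with `data` (4D array), `affine` (4 x 4),
#'   `voxel_mm`, and `scheme` (a [gradient_scheme()] or `NULL`).
#' @export
read_dwi <- function(path, bval_path = NULL, bvec_path = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  affine <- unclass(RNifti::xform(img))
  voxel_mm <- abs(RNifti::pixdim(img))[1:3]
  scheme <- NULL
  if (!is.null(bval_path)) {
    scheme <- read_bvals_bvecs(bval_path, bvec_path)
    nv <- if (length(dim(data)) == 4L) dim(data)[4] else 1L
    if (length(scheme$bvals) != nv) {
      stop_tendtract("bad_input",
                     "gradient table lists %d volumes but the image has %d",
                     length(scheme$bvals), nv)
    }
  }
  list(data = data, affine = affine, voxel_mm = voxel_mm, scheme = scheme)
}

#' @rdname read_dwi
#' @param data numeric array (3D or 4D) to write.
#' @param voxel_mm voxel size, mm.
#' @param affine 4 x 4 voxel-to-world matrix (defaults to scaled identity).
#' @param scheme optional [gradient_scheme()]; when given, `.bval`/`.bvec`
#'   files are written next to the image.
#' @export
write_dwi <- function(data, path, voxel_mm = 2.5, affine = NULL, scheme = NULL) {
  voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3L)
  if (is.null(affine)) affine <- diag(c(voxel_mm, 1))
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (!is.null(scheme)) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    write_bvals_bvecs(scheme, paste0(stem, ".bval"), paste0(stem, ".bvec"))
  }
  invisible(path)
}

#' Write / read streamline bundles (TCK or TRK)
#'
#' The format follows the file extension: `.tck` (MRtrix track file;
#' world-mm Float32 triplets, streamlines separated by NaN, file
#' terminated by Inf) or `.trk` (TrackVis, version 2), which additionally
#' stores the per-point FA samples as a scalar channel named `fa`. TCK has
#' no per-point scalar channel, so FA samples are not preserved there.
#'
#' @param bundles a `tract_bundle`, a list of them, or a list of
#'   `streamline` objects.
#' @param path output path ending in `.tck` or `.trk`.
#' @param voxel_mm,dim,affine image geometry recorded in the TRK header
#'   (ignored for TCK).
#' @return `write_streamlines` returns the path invisibly;
#'   `read_streamlines` returns a `tract_bundle` holding all streamlines
#'   in file order (FA filled from the scalar channel when present).
#' @export
write_streamlines <- function(bundles, path, voxel_mm = 2.5,
                              dim = c(1L, 1L, 1L), affine = NULL) {
  sls <- collect_streamlines(bundles)
  ext <- tolower(tools::file_ext(path))
  if (ext == "tck") {
    write_tck(sls, path)
  } else if (ext == "trk") {
    voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3L)
    if (is.null(affine)) affine <- diag(c(voxel_mm, 1))
    write_trk(sls, path, voxel_mm, as.integer(dim), affine)
  } else {
    stop_tendtract("bad_format",
                   "unknown streamline extension '.%s'; supported: .tck, .trk", ext)
  }
  invisible(path)
}

collect_streamlines <- function(bundles) {
  if (inherits(bundles, "tract_bundle")) return(bundles$streamlines)
  if (inherits(bundles, "streamline")) return(list(bundles))
  out <- list()
  for (b in bundles) {
    out <- c(out, if (inherits(b, "tract_bundle")) b$streamlines else list(b))
  }
  out
}

write_tck <- function(sls, path) {
  offset <- 200L   # fixed data offset; header is padded up to it
  hdr <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", length(sls),
                "\nfile: . ", offset, "\nEND\n")
  pad <- offset - nchar(hdr, type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(rep(as.raw(10L), pad), con)
  for (s in sls) {
    writeBin(as.numeric(t(s$points)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    line <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "\n") break
      line <- paste0(line, ch)
    }
    if (line == "END") break
    lines <- c(lines, line)
  }
  kv <- strsplit(lines[-1], ": ")
  keys <- vapply(kv, `[`, "", 1)
  offset <- as.integer(trimws(strsplit(kv[[which(keys == "file")]][2], " ")[[1]][2]))
  seek(con, offset)
  raw_f <- readBin(con, numeric(), n = file.size(path), size = 4, endian = "little")
  pts <- matrix(raw_f, ncol = 3, byrow = TRUE)
  sls <- list()
  cur <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (all(is.infinite(pts[i, ]))) break
    if (all(is.nan(pts[i, ]))) {
      if (length(cur) > 0) {
        p <- pts[cur, , drop = FALSE]
        sls[[length(sls) + 1L]] <- new_streamline(p, rep(NA_real_, nrow(p)))
      }
      cur <- integer(0)
    } else {
      cur <- c(cur, i)
    }
  }
  sls
}

write_trk <- function(sls, path, voxel_mm, dim, affine) {
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, width) {
    r <- charToRaw(s)
    writeBin(c(r, rep(as.raw(0), width - length(r))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_mm), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")  # origin
  writeBin(1L, con, size = 2, endian = "little")         # n_scalars
  wchar("fa", 20); for (i in 2:10) wchar("", 20)
  writeBin(0L, con, size = 2, endian = "little")         # n_properties
  for (i in 1:10) wchar("", 20)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")  # vox_to_ras, row-major
  writeBin(rep(as.raw(0), 444), con)
  wchar("RAS", 4); wchar("", 4)
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(rep(as.raw(0), 2 + 6), con)
  writeBin(length(sls), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")         # version
  writeBin(1000L, con, size = 4, endian = "little")      # hdr_size
  inv <- solve(affine)
  for (s in sls) {
    np <- nrow(s$points)
    writeBin(np, con, size = 4, endian = "little")
    vox <- cbind(s$points, 1) %*% t(inv)                 # fractional voxel
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, voxel_mm, "*")
    dat <- cbind(voxmm, s$fa)
    writeBin(as.numeric(t(dat)), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), 6)
  dim <- readBin(con, integer(), 3, size = 2, endian = "little")
  voxel_mm <- readBin(con, numeric(), 3, size = 4, endian = "little")
  readBin(con, numeric(), 3, size = 4, endian = "little")
  n_scalars <- readBin(con, integer(), 1, size = 2, endian = "little")
  readBin(con, raw(), 200)
  n_props <- readBin(con, integer(), 1, size = 2, endian = "little")
  readBin(con, raw(), 200)
  affine <- matrix(readBin(con, numeric(), 16, size = 4, endian = "little"), 4, 4, byrow = TRUE)
  readBin(con, raw(), 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, integer(), 1, size = 4, endian = "little")
  readBin(con, integer(), 2, size = 4, endian = "little")
  sls <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, integer(), 1, size = 4, endian = "little")
    dat <- matrix(readBin(con, numeric(), np * (3 + n_scalars + 0), size = 4,
                          endian = "little"),
                  np, 3 + n_scalars, byrow = TRUE)
    if (n_props > 0) readBin(con, numeric(), n_props, size = 4)
    vox <- sweep(dat[, 1:3, drop = FALSE], 2, voxel_mm, "/") - 0.5
    world <- cbind(vox, 1) %*% t(affine)
    fa <- if (n_scalars >= 1) dat[, 4] else rep(NA_real_, np)
    sls[[i]] <- new_streamline(world[, 1:3, drop = FALSE], fa)
  }
  sls
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sls <- if (ext == "tck") read_tck(path)
         else if (ext == "trk") read_trk(path)
         else stop_tendtract("bad_format",
                             "unknown streamline extension '.%s'; supported: .tck, .trk", ext)
  structure(list(parcel = NA_integer_, name = basename(path),
                 subject = NA_character_, streamlines = sls),
            class = "tract_bundle")
}
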