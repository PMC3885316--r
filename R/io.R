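# Text interchange formats: Gaussian cube grids, TSV mode tables, TSV
# dipole-vs-field samples, JSON tensor reports. All values round-trip at
# full stored precision; no bespoke binary formats.

#' Write a density grid as a Gaussian cube file
#'
#' Standard cube layout (two title lines; natoms + origin; three axis
#' lines; atom block; values with the last axis fastest), written at full
#' precision so that read/write round-trips are lossless. The applied-field
#' tag is stored in the first title line as `F= fx fy fz`.
#'
#' @param gd A [grid_density()] (or `hyper_density`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(gd, path) {
  stopifnot(inherits(gd, "grid_density"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s F= %.12g %.12g %.12g", gd$title,
                     gd$field[1], gd$field[2], gd$field[3]), con)
  writeLines("written by hyperpol", con)
  atoms <- gd$atoms
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)
  writeLines(sprintf("%5d %.16e %.16e %.16e", natoms,
                     gd$origin[1], gd$origin[2], gd$origin[3]), con)
  for (i in 1:3)
    writeLines(sprintf("%5d %.16e %.16e %.16e", gd$counts[i],
                       gd$axes[i, 1], gd$axes[i, 2], gd$axes[i, 3]), con)
  if (natoms > 0)
    for (r in seq_len(natoms))
      writeLines(sprintf("%5d %.16e %.16e %.16e %.16e", atoms$Z[r],
                         atoms$charge[r], atoms$x[r], atoms$y[r], atoms$z[r]), con)
  # values: x outer, z fastest, 6 per line
  v <- gd$values
  flat <- as.numeric(aperm(v, c(3, 2, 1)))   # z fastest when x varies slowest
  idx <- seq(1, length(flat), by = 6)
  for (s in idx) {
    e <- min(s + 5, length(flat))
    writeLines(paste(sprintf("% .16e", flat[s:e]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' Supports the standard dialect rule on voxel counts: positive counts mean
#' axis vectors in bohr, negative counts mean Angstrom (converted to bohr
#' on read and recorded in the `units_detected` attribute). A field tag
#' `F= fx fy fz` in the title line is recovered; truncated files raise an
#' error rather than returning partial data.
#'
#' @param path Cube file path.
#' @return A [grid_density()].
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("read_cube: truncated header in ", path, call. = FALSE)
  title <- lines[1]
  field <- c(0, 0, 0)
  fm <- regmatches(title, regexec("F=\\s*(\\S+)\\s+(\\S+)\\s+(\\S+)", title))[[1]]
  if (length(fm) == 4) {
    field <- as.numeric(fm[2:4])
    title <- trimws(sub("F=.*$", "", title))
  }
  toks <- function(i) {
    t <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    suppressWarnings(as.numeric(t))
  }
  l3 <- toks(3)
  if (length(l3) < 4 || anyNA(l3[1:4]))
    stop("read_cube: malformed header at line 3 of ", path, call. = FALSE)
  natoms <- as.integer(l3[1]); origin <- l3[2:4]
  counts <- integer(3); axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    li <- toks(3 + i)
    if (length(li) < 4 || anyNA(li[1:4]))
      stop("read_cube: malformed axis at line ", 3 + i, " of ", path, call. = FALSE)
    counts[i] <- as.integer(li[1]); axes[i, ] <- li[2:4]
  }
  units_detected <- "bohr"
  if (any(counts < 0)) {
    units_detected <- "angstrom"
    conv <- 1 / unit_constants()$bohr_angstrom
    axes <- axes * conv
    origin <- origin * conv
    counts <- abs(counts)
  }
  atoms <- NULL
  at0 <- 7L
  if (natoms > 0) {
    rows <- lapply(seq_len(natoms), function(r) toks(6 + r))
    atoms <- data.frame(Z = vapply(rows, function(x) as.integer(x[1]), 1L),
                        charge = vapply(rows, `[`, 0, 2),
                        x = vapply(rows, `[`, 0, 3),
                        y = vapply(rows, `[`, 0, 4),
                        z = vapply(rows, `[`, 0, 5))
    at0 <- at0 + natoms
  }
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[at0:length(lines)]), "\\s+"))))
  nexp <- prod(counts)
  if (length(vals) != nexp || anyNA(vals))
    stop("read_cube: expected ", nexp, " values, found ", length(vals),
         " (file ", path, ", values start line ", at0, ")", call. = FALSE)
  v <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  gd <- grid_density(origin, axes, v, field = field, atoms = atoms, title = title)
  attr(gd, "units_detected") <- units_detected
  gd
}

# ---- mode tables -----------------------------------------------------------

.MODE_COLS <- c("index", "wavenumber_cm1", "dmu_x", "dmu_y", "dmu_z",
                "dalpha_xx", "dalpha_xy", "dalpha_xz",
                "dalpha_yy", "dalpha_yz", "dalpha_zz", "label")

#' Write a normal-mode table as TSV
#'
#' Columns: index, wavenumber_cm1, dmu_x..z, dalpha_xx..zz (six unique
#' symmetric components), label. Derivatives in a.u. per mass-weighted
#' a.u. coordinate.
#'
#' @param modes List of [normal_mode()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mode_table <- function(modes, path) {
  rows <- lapply(modes, function(m) {
    da <- m$dalpha
    data.frame(index = m$index, wavenumber_cm1 = m$wavenumber,
               dmu_x = m$dmu[1], dmu_y = m$dmu[2], dmu_z = m$dmu[3],
               dalpha_xx = da[1, 1], dalpha_xy = da[1, 2], dalpha_xz = da[1, 3],
               dalpha_yy = da[2, 2], dalpha_yz = da[2, 3], dalpha_zz = da[3, 3],
               label = m$label, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a normal-mode table from TSV
#'
#' @param path TSV path in the [write_mode_table()] layout.
#' @return List of [normal_mode()] objects.
#' @export
read_mode_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(setdiff(.MODE_COLS, "label"), names(df))
  if (length(missing))
    stop("read_mode_table: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(df$label)) df$label <- ""
  lapply(seq_len(nrow(df)), function(r) {
    da <- matrix(0, 3, 3)
    da[1, 1] <- df$dalpha_xx[r]; da[2, 2] <- df$dalpha_yy[r]; da[3, 3] <- df$dalpha_zz[r]
    da[1, 2] <- da[2, 1] <- df$dalpha_xy[r]
    da[1, 3] <- da[3, 1] <- df$dalpha_xz[r]
    da[2, 3] <- da[3, 2] <- df$dalpha_yz[r]
    normal_mode(df$index[r], df$wavenumber_cm1[r],
                c(df$dmu_x[r], df$dmu_y[r], df$dmu_z[r]), da, df$label[r])
  })
}

# ---- dipole samples --------------------------------------------------------

#' Write dipole-vs-field samples as TSV
#'
#' Columns Fx, Fy, Fz, mu_x, mu_y, mu_z (a.u.); stencil parameters and
#' provenance are stored in `#`-prefixed header comments so the stencil can
#' be reconstructed on read.
#'
#' @param samples A [dipole_samples()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dipole_samples <- function(samples, path) {
  stopifnot(inherits(samples, "dipole_samples"))
  st <- samples$stencil
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# provenance: %s", samples$provenance),
               sprintf("# stencil: base=%.12g depth=%d ladder=%.12g axes=%s max_order=%d",
                       st$base, st$depth, st$ladder,
                       paste(names(.AXES)[st$axes], collapse = ""), st$max_order),
               paste(c("Fx", "Fy", "Fz", "mu_x", "mu_y", "mu_z"), collapse = "\t")), con)
  for (r in seq_len(nrow(samples$fields)))
    writeLines(paste(sprintf("%.17g", c(samples$fields[r, ], samples$mu[r, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read dipole-vs-field samples from TSV
#'
#' Validates stencil closure (zero field present; for every F, -F present)
#' and rebuilds the stencil from the header comment.
#'
#' @param path TSV path in the [write_dipole_samples()] layout.
#' @return A [dipole_samples()] object.
#' @export
read_dipole_samples <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  prov <- "external"
  pm <- grep("provenance:", hdr, value = TRUE)
  if (length(pm)) prov <- trimws(sub(".*provenance:", "", pm[1]))
  sm <- grep("stencil:", hdr, value = TRUE)
  if (!length(sm))
    stop("read_dipole_samples: missing '# stencil:' header in ", path, call. = FALSE)
  gv <- function(key, s) as.numeric(sub(paste0(".*", key, "=([-0-9.eE+]+).*"), "\\1", s))
  base <- gv("base", sm); depth <- as.integer(gv("depth", sm))
  ladder <- gv("ladder", sm); max_order <- as.integer(gv("max_order", sm))
  axes <- strsplit(sub(".*axes=([xyz]+).*", "\\1", sm), "")[[1]]
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t", header = TRUE)
  st <- build_stencil(base, depth, axes, max_order, ladder)
  keys_file <- apply(as.matrix(df[, 1:3]), 1, .fkey)
  keys_st <- apply(st$fields, 1, .fkey)
  if (!all(keys_st %in% keys_file))
    stop("read_dipole_samples: file does not cover the declared stencil (missing ",
         sum(!(keys_st %in% keys_file)), " points)", call. = FALSE)
  # closure check on the file itself
  neg <- apply(-as.matrix(df[, 1:3]), 1, .fkey)
  if (!all(neg %in% keys_file))
    stop("read_dipole_samples: sample set is not closed under sign inversion",
         call. = FALSE)
  mu <- as.matrix(df[match(keys_st, keys_file), 4:6])
  dimnames(mu) <- NULL
  dipole_samples(st, mu, provenance = if (prov == "synthetic") "synthetic" else "external")
}

# ---- tensor JSON -----------------------------------------------------------

#' Write a dipole/beta response report as JSON
#'
#' Explicit keys (`mu_x`..., `beta_xxx`...`beta_zzz`), a mandatory `units`
#' field and a phase label.
#'
#' @param path Output path.
#' @param phase Phase label, e.g. `"gas"` or `"water"`.
#' @param mu Optional [dipole()].
#' @param beta Optional [beta_tensor()].
#' @param units Units list; defaults to the objects' native units.
#' @return `path`, invisibly.
#' @export
write_response_json <- function(path, phase, mu = NULL, beta = NULL, units = NULL) {
  out <- list(phase = phase)
  if (is.null(units)) units <- list()
  if (!is.null(mu)) {
    out$mu_x <- mu$mu[1]; out$mu_y <- mu$mu[2]; out$mu_z <- mu$mu[3]
    units$mu <- mu$units
  }
  if (!is.null(beta)) {
    ax <- names(.AXES)
    for (i in 1:3) for (j in 1:3) for (k in 1:3)
      out[[paste0("beta_", ax[i], ax[j], ax[k])]] <- beta$b[i, j, k]
    out$beta_symmetry <- beta$symmetry
    if (is.null(units$beta)) units$beta <- "au"
  }
  out$units <- units
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a response report written by [write_response_json()]
#'
#' @param path JSON path.
#' @return List with `phase`, `units`, and any of `mu` ([dipole()]) and
#'   `beta` ([beta_tensor()]).
#' @export
read_response_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$units)) stop("read_response_json: missing units field", call. = FALSE)
  out <- list(phase = x$phase, units = x$units)
  if (!is.null(x$mu_x))
    out$mu <- dipole(c(x$mu_x, x$mu_y, x$mu_z),
                     units = if (!is.null(x$units$mu)) x$units$mu else "au")
  if (!is.null(x$beta_xxx)) {
    ax <- names(.AXES)
    arr <- array(0, c(3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
      key <- paste0("beta_", ax[i], ax[j], ax[k])
      if (!is.null(x[[key]])) arr[i, j, k] <- x[[key]]
    }
    sym <- if (!is.null(x$beta_symmetry)) x$beta_symmetry else "kleinman"
    out$beta <- beta_tensor(arr, symmetry = sym)
  }
  out
}
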