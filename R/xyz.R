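#' @title Snapshots and extended-XYZ trajectory I/O
#' @name xyz
#' @description
#' A `Snapshot` is the shared configuration container of the MD and bridging
#' modules: bead coordinates (Angstrom), species labels, chain ids (NA for
#' free ions), and a periodic box. Trajectories are stored in an extended-XYZ
#' dialect: per frame, an atom-count line, a comment line carrying
#' `box="Lx Ly Lz"`, then one row per bead with columns
#' `species chain x y z` (chain `-` for ions).
NULL

#' Construct a snapshot
#'
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param species character vector length n.
#' @param chain integer vector length n (NA for non-chain species).
#' @param box numeric length 3 (Lx, Ly, Lz), Angstrom.
#' @param wrap logical: wrap coordinates into the box.
#' @return a `Snapshot`.
#' @export
snapshot <- function(coords, species, chain = rep(NA_integer_, nrow(coords)),
                     box, wrap = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(species) == nrow(coords),
            length(chain) == nrow(coords), length(box) == 3, all(box > 0))
  if (wrap) coords <- sweep(coords, 2, box, function(x, L) x %% L)
  structure(list(coords = coords, species = as.character(species),
                 chain = as.integer(chain), box = as.numeric(box)),
            class = "Snapshot")
}

#' @export
print.Snapshot <- function(x, ...) {
  cat("Snapshot:", nrow(x$coords), "beads,",
      length(unique(stats::na.omit(x$chain))), "chains, box",
      paste(signif(x$box, 5), collapse = " x "), "A\n")
  invisible(x)
}

#' Write snapshots to an extended-XYZ file
#'
#' @param snapshots a `Snapshot` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(snapshots, path) {
  if (inherits(snapshots, "Snapshot")) snapshots <- list(snapshots)
  con <- file(path, "w")
  on.exit(close(con))
  for (sn in snapshots) {
    n <- nrow(sn$coords)
    writeLines(as.character(n), con)
    writeLines(sprintf('box="%.8g %.8g %.8g"', sn$box[1], sn$box[2],
                       sn$box[3]), con)
    ch <- ifelse(is.na(sn$chain), "-", as.character(sn$chain))
    writeLines(sprintf("%s %s %.8g %.8g %.8g", sn$species, ch,
                       sn$coords[, 1], sn$coords[, 2], sn$coords[, 3]), con)
  }
  invisible(path)
}

#' Read snapshots from an extended-XYZ file
#'
#' Validates per-frame atom counts and requires the `box` attribute and the
#' chain column.
#'
#' @param path input file.
#' @return list of `Snapshot` objects.
#' @export
read_snapshots <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0) stop("bad atom count at line ", i)
    if (i + 1L + n > length(lines) + 0L)
      stop("frame at line ", i, " truncated: expected ", n, " atom rows")
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexec('box="([^"]+)"', comment))[[1]]
    if (length(m) < 2) stop("missing box=\"Lx Ly Lz\" in comment at line ",
                            i + 1L)
    box <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
    if (length(box) != 3 || any(!is.finite(box)))
      stop("malformed box at line ", i + 1L)
    rows <- strsplit(trimws(lines[i + 2L:(n + 1L)]), "\\s+")
    nf <- lengths(rows)
    if (any(nf != 5))
      stop("expected 5 columns (species chain x y z) at line ",
           i + 1L + which(nf != 5)[1],
           if (any(nf == 4)) ": missing chain column" else "")
    species <- vapply(rows, `[[`, character(1), 1)
    chain_s <- vapply(rows, `[[`, character(1), 2)
    chain <- suppressWarnings(as.integer(chain_s))
    coords <- matrix(as.numeric(vapply(rows, function(r) r[3:5],
                                       character(3))),
                     ncol = 3, byrow = TRUE)
    if (any(!is.finite(coords))) stop("non-numeric coordinate near line ", i)
    out[[length(out) + 1L]] <- snapshot(coords, species, chain, box,
                                        wrap = FALSE)
    i <- i + 2L + n
  }
  if (!length(out)) stop("no frames in ", path)
  out
}

# minimum-image displacement matrix utilities
.min_image <- function(dx, L) dx - L * round(dx / L)

# pairwise minimum-image distances between two coordinate sets (na x nb)
.pdist_pbc <- function(a, b, box) {
  dx <- .min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- .min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- .min_image(outer(a[, 3], b[, 3], "-"), box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}
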