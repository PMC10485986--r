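#' Construct a landmark set
#'
#' A `landmark_set` holds raw (unaligned) 3-D landmark configurations for a
#' set of taxa, together with landmark labels and the assignment of each
#' landmark to an anatomical module (e.g. a skull element). Coordinates are
#' treated as dimensionless after reading; original units are metadata only.
#'
#' @param coords numeric array `n_taxa x n_landmarks x 3`.
#' @param taxa character vector of taxon names (length `n_taxa`), no
#'   duplicates.
#' @param module_of character vector (length `n_landmarks`) giving the module
#'   name of each landmark; every landmark must have exactly one assignment.
#' @param landmark_labels optional character vector of landmark names.
#' @param units free-text unit annotation (default `"unknown"`).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, taxa = NULL, module_of = NULL,
                         landmark_labels = NULL, units = "unknown") {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop_validation("coords must be an n_taxa x n_landmarks x 3 array")
  n <- dim(coords)[1]; p <- dim(coords)[2]
  taxa <- taxa %||% dimnames(coords)[[1]] %||% paste0("t", seq_len(n))
  if (length(taxa) != n)
    stop_validation("taxa length (%d) does not match coords (%d rows)",
                    length(taxa), n)
  if (anyDuplicated(taxa))
    stop_validation("duplicate taxon names: %s",
                    paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyNA(coords))
    stop_validation("NaN/NA coordinates present (first bad taxon: %s)",
                    taxa[which(apply(is.na(coords), 1, any))[1]])
  module_of <- module_of %||% rep("all", p)
  if (length(module_of) != p || anyNA(module_of))
    stop_validation("module_of must assign every one of the %d landmarks", p)
  landmark_labels <- landmark_labels %||% paste0("lm", seq_len(p))
  dimnames(coords) <- list(taxa, landmark_labels, c("x", "y", "z"))
  structure(list(coords = coords, taxa = taxa,
                 landmark_labels = landmark_labels,
                 module_of = as.character(module_of), units = units),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d taxa, %d landmarks, %d module(s): %s\n",
              length(x$taxa), length(x$landmark_labels),
              length(unique(x$module_of)),
              paste(unique(x$module_of), collapse = ", ")))
  invisible(x)
}

#' Number of taxa / landmarks in a landmark set
#' @param x a `landmark_set`.
#' @return integer count.
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname n_taxa
#' @export
n_landmarks <- function(x) length(x$landmark_labels)

#' Subset a landmark set to one module
#'
#' @param x a `landmark_set`.
#' @param module module name appearing in `x$module_of`.
#' @return a `landmark_set` containing only that module's landmarks.
#' @export
module_subset <- function(x, module) {
  keep <- which(x$module_of == module)
  if (!length(keep)) stop_validation("unknown module '%s'", module)
  landmark_set(x$coords[, keep, , drop = FALSE], x$taxa,
               module_of = x$module_of[keep],
               landmark_labels = x$landmark_labels[keep], units = x$units)
}

#' Subset a landmark set to given taxa (in the given order)
#' @param x a `landmark_set`.
#' @param taxa character vector of taxon names to retain, in desired order.
#' @return a `landmark_set`.
#' @export
taxon_subset <- function(x, taxa) {
  idx <- match(taxa, x$taxa)
  if (anyNA(idx))
    stop_validation("taxa not present: %s",
                    paste(taxa[is.na(idx)], collapse = ", "))
  landmark_set(x$coords[idx, , , drop = FALSE], x$taxa[idx],
               module_of = x$module_of,
               landmark_labels = x$landmark_labels, units = x$units)
}

#' Read landmark configurations from a TPS or wide-CSV file
#'
#' The TPS dialect uses `LM3=<n>` blocks with one `x y z` line per landmark
#' and an `ID=<taxon>` line per specimen; `SCALE=` lines are ignored with a
#' warning. The CSV dialect has one row per taxon with a leading `taxon`
#' column and columns `x1,y1,z1,...` in landmark order.
#'
#' @param path file path.
#' @param format `"tps"`, `"csv"`, or `"auto"` (by extension).
#' @param module_of optional module assignment to attach (see
#'   [read_module_map()]).
#' @return a [landmark_set()].
#' @export
read_landmark_file <- function(path, format = c("auto", "tps", "csv"),
                               module_of = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  if (format == "tps") .read_tps(path, module_of) else .read_lm_csv(path, module_of)
}

.read_tps <- function(path, module_of) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop_validation("no LM3= blocks in %s", path)
  taxa <- character(0); cfg <- list(); p0 <- NA_integer_
  bounds <- c(starts, length(lines) + 1L)
  for (b in seq_along(starts)) {
    blk <- lines[bounds[b]:(bounds[b + 1L] - 1L)]
    p <- as.integer(sub("^LM3\\s*=\\s*", "", blk[1], ignore.case = TRUE))
    id_line <- grep("^ID\\s*=", blk, ignore.case = TRUE)
    taxon <- if (length(id_line)) sub("^ID\\s*=\\s*", "", blk[id_line[1]],
                                      ignore.case = TRUE)
             else paste0("specimen", b)
    if (any(grepl("^SCALE\\s*=", blk, ignore.case = TRUE)))
      warning("SCALE= line ignored for taxon ", taxon)
    coord_lines <- blk[-c(1L, grep("^(ID|SCALE|IMAGE)\\s*=", blk,
                                   ignore.case = TRUE))]
    if (length(coord_lines) != p)
      stop_validation("taxon '%s': LM3=%d but %d coordinate lines",
                      taxon, p, length(coord_lines))
    m <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    if (ncol(m) != 3 || anyNA(m))
      stop_validation("taxon '%s': malformed 3-D coordinate line", taxon)
    if (is.na(p0)) p0 <- p
    if (p != p0)
      stop_validation("inconsistent landmark count for taxon '%s' (%d vs %d)",
                      taxon, p, p0)
    if (taxon %in% taxa) stop_validation("duplicate taxon '%s'", taxon)
    taxa <- c(taxa, taxon); cfg[[taxon]] <- m
  }
  coords <- aperm(simplify2array(cfg), c(3, 1, 2))  # n x p x 3
  landmark_set(coords, taxa, module_of = module_of)
}

.read_lm_csv <- function(path, module_of) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  taxa <- as.character(df[[1]])
  if (anyDuplicated(taxa))
    stop_validation("duplicate taxon '%s'", taxa[duplicated(taxa)][1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(vals) %% 3 != 0)
    stop_validation("CSV landmark file: %d coordinate columns not divisible by 3",
                    ncol(vals))
  p <- ncol(vals) / 3
  if (anyNA(vals)) {
    bad <- taxa[which(apply(is.na(vals), 1, any))[1]]
    stop_validation("non-numeric or missing coordinate for taxon '%s'", bad)
  }
  coords <- array(NA_real_, c(nrow(vals), p, 3))
  for (k in 1:3) coords[, , k] <- vals[, seq(k, ncol(vals), by = 3)]
  landmark_set(coords, taxa, module_of = module_of)
}

#' Write a landmark set to TPS or wide CSV
#'
#' Inverse of [read_landmark_file()]; round-trips coordinates at full double
#' precision.
#'
#' @param x a `landmark_set`.
#' @param path output path.
#' @param format `"tps"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_landmark_file <- function(x, path, format = c("tps", "csv")) {
  format <- match.arg(format)
  if (format == "tps") {
    con <- file(path, "w"); on.exit(close(con))
    p <- n_landmarks(x)
    for (i in seq_len(n_taxa(x))) {
      writeLines(sprintf("LM3=%d", p), con)
      writeLines(apply(format(x$coords[i, , , drop = TRUE],
                              digits = 17, trim = TRUE, scientific = FALSE),
                       1, paste, collapse = " "), con)
      writeLines(sprintf("ID=%s", x$taxa[i]), con)
    }
  } else {
    p <- n_landmarks(x)
    # columns ordered x1,y1,z1,x2,...
    flat <- do.call(cbind, lapply(seq_len(p), function(j)
      cbind(x$coords[, j, 1], x$coords[, j, 2], x$coords[, j, 3])))
    colnames(flat) <- as.vector(t(outer(seq_len(p), c("x", "y", "z"),
                                        function(j, a) paste0(a, j))))
    df <- data.frame(taxon = x$taxa, flat, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a landmark-to-module assignment file
#'
#' CSV dialect: columns `landmark` (0-based index) and `module`. YAML dialect:
#' a mapping from 0-based landmark index to module name, or a mapping from
#' module name to a list of 0-based indices.
#'
#' @param path file path (`.csv`, `.yml`, `.yaml`).
#' @param n_landmarks expected landmark count; an error is raised if the file
#'   does not cover exactly this many landmarks.
#' @return character vector of module names, one per landmark, in landmark
#'   order.
#' @export
read_module_map <- function(path, n_landmarks = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (all(vapply(y, length, 1L) == 1L) &&
        !anyNA(suppressWarnings(as.integer(names(y))))) {
      idx <- as.integer(names(y)); mod <- unlist(y, use.names = FALSE)
    } else {
      mod <- rep(names(y), vapply(y, length, 1L))
      idx <- as.integer(unlist(y, use.names = FALSE))
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    idx <- as.integer(df$landmark); mod <- as.character(df$module)
  }
  if (anyNA(idx) || anyDuplicated(idx))
    stop_validation("module map must give each landmark index exactly once")
  out <- character(length(idx))
  out[idx + 1L] <- mod
  if (!is.null(n_landmarks) && length(out) != n_landmarks)
    stop_validation("module map covers %d landmarks, expected %d",
                    length(out), n_landmarks)
  if (any(!nzchar(out)))
    stop_validation("module map has gaps in landmark indices")
  out
}

#' Write a landmark-to-module assignment file (CSV, 0-based indices)
#' @param module_of character vector of module names in landmark order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_map <- function(module_of, path) {
  utils::write.csv(data.frame(landmark = seq_along(module_of) - 1L,
                              module = module_of),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
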