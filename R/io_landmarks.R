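#' @importFrom stats cov lm lowess optim quantile rnorm runif sd var coef setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- core containers --------------------------------------------------------

#' Construct a single landmark configuration
#'
#' A configuration is a k x d matrix of Cartesian coordinates with one row per
#' named landmark.  Coordinates are kept in input units; nothing is centered
#' or scaled at construction time.
#'
#' @param coords numeric k x d matrix (d = 2 or 3).
#' @param labels character vector of k unique landmark names; defaults to
#'   rownames of `coords` or `p1..pk`.
#' @param specimen_id single string identifying the specimen.
#' @return an object of class `landmark_config` (a matrix with attributes).
#' @export
landmark_config <- function(coords, labels = NULL, specimen_id = "specimen") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  k <- nrow(coords); d <- ncol(coords)
  if (!d %in% c(2L, 3L)) stop("landmark dimension must be 2 or 3, got ", d)
  if (any(!is.finite(coords))) stop("non-finite coordinate in configuration '", specimen_id, "'")
  if (is.null(labels)) labels <- rownames(coords)
  if (is.null(labels)) labels <- paste0("p", seq_len(k))
  labels <- as.character(labels)
  if (length(labels) != k) stop("need ", k, " labels, got ", length(labels))
  if (anyDuplicated(labels)) stop("duplicated landmark label: ",
                                  labels[duplicated(labels)][1])
  dimnames(coords) <- list(labels, c("x", "y", "z")[seq_len(d)])
  structure(coords, specimen_id = as.character(specimen_id),
            class = c("landmark_config", "matrix", "array"))
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", attr(x, "specimen_id"), "': ",
      nrow(x), " landmarks in ", ncol(x), "D\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

landmark_labels <- function(x) rownames(x)

#' Bundle configurations into a sample
#'
#' All configurations must share the landmark count, dimension, and label
#' order.  Stored as a k x d x n array (one slice per specimen).
#'
#' @param configs list of `landmark_config` objects (or k x d matrices).
#' @param specimen_ids optional character vector overriding per-config ids.
#' @return object of class `landmark_sample` with fields `coords` (k x d x n
#'   array), `labels`, `specimen_ids`.
#' @export
landmark_sample <- function(configs, specimen_ids = NULL) {
  if (!length(configs)) stop("a landmark sample needs n >= 1 configurations")
  configs <- lapply(seq_along(configs), function(i) {
    ci <- configs[[i]]
    if (inherits(ci, "landmark_config")) ci
    else landmark_config(ci, specimen_id = paste0("s", i))
  })
  k <- nrow(configs[[1]]); d <- ncol(configs[[1]])
  lab <- landmark_labels(configs[[1]])
  for (i in seq_along(configs)) {
    ci <- configs[[i]]
    if (nrow(ci) != k || ncol(ci) != d)
      stop("configuration ", i, " has ", nrow(ci), "x", ncol(ci),
           " coordinates; expected ", k, "x", d)
    if (!identical(landmark_labels(ci), lab))
      stop("configuration ", i, " has a different landmark label order")
  }
  ids <- if (is.null(specimen_ids))
    vapply(configs, attr, "", which = "specimen_id") else as.character(specimen_ids)
  if (length(ids) != length(configs)) stop("specimen_ids length mismatch")
  arr <- array(unlist(lapply(configs, unclass), use.names = FALSE),
               dim = c(k, d, length(configs)),
               dimnames = list(lab, c("x", "y", "z")[seq_len(d)], ids))
  structure(list(coords = arr, labels = lab, specimen_ids = ids),
            class = "landmark_sample")
}

#' @export
print.landmark_sample <- function(x, ...) {
  dm <- dim(x$coords)
  cat("Landmark sample: n =", dm[3], "specimens,", dm[1], "landmarks,",
      dm[2], "D\n")
  invisible(x)
}

#' @export
length.landmark_sample <- function(x) dim(x$coords)[3]

#' Extract one configuration from a sample
#' @param x a `landmark_sample`
#' @param i specimen index or id
#' @param ... unused
#' @export
`[[.landmark_sample` <- function(x, i, ...) {
  landmark_config(x$coords[, , i, drop = TRUE], labels = x$labels,
                  specimen_id = if (is.character(i)) i else x$specimen_ids[i])
}

n_landmarks <- function(x) {
  if (inherits(x, "landmark_sample")) dim(x$coords)[1] else nrow(x)
}
n_dim <- function(x) {
  if (inherits(x, "landmark_sample")) dim(x$coords)[2] else ncol(x)
}

# configuration matrix <-> interleaved shape vector (x1,y1,x2,y2,...)
config_to_vec <- function(m) as.vector(t(unclass(m)))
vec_to_config <- function(v, d = 2L, labels = NULL, specimen_id = "form") {
  landmark_config(matrix(v, ncol = d, byrow = TRUE), labels = labels,
                  specimen_id = specimen_id)
}

# n x (k*d) matrix of interleaved shape vectors for a sample
sample_to_matrix <- function(s) {
  dm <- dim(s$coords)
  t(apply(s$coords, 3, function(m) as.vector(t(m))))
}

# ---- TPS files --------------------------------------------------------------

#' Read landmark data from a TPS or CSV file
#'
#' The TPS dialect understood is the common digitizer output: `LM=k` followed
#' by k coordinate lines (`LM3=k` for 3D), optional `ID=` and `SCALE=`
#' records.  `SCALE=` is applied multiplicatively on read.  Curve records
#' (`CURVES=`/`POINTS=`) are skipped with a warning.  The CSV layout is one
#' row per specimen: a leading `specimen_id` column and then
#' `label_x,label_y[,label_z]` column pairs/triples.
#'
#' @param path file path.
#' @param format `"tps"` or `"csv"`; guessed from the extension by default.
#' @return a [landmark_sample()].
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tps"
  if (format == "tps") read_tps(path) else read_landmarks_csv(path)
}

read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  configs <- list(); i <- 1L; nrec <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^LM(3?)\\s*=\\s*([0-9]+)\\s*$", ln,
                                ignore.case = TRUE))[[1]]
    if (!length(m)) stop("TPS parse error at line ", i, ": expected LM= record, got '",
                         ln, "'")
    d <- if (m[2] == "3") 3L else 2L
    k <- as.integer(m[3])
    if (k < 1) stop("TPS parse error at line ", i, ": LM count must be >= 1")
    if (i + k > length(lines)) stop("TPS parse error: LM=", k,
                                    " at line ", i, " but file ends early")
    coords <- matrix(NA_real_, k, d)
    for (j in seq_len(k)) {
      fields <- strsplit(trimws(lines[i + j]), "[[:space:],]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != d || any(is.na(vals)))
        stop("TPS parse error at line ", i + j, ": expected ", d,
             " numeric coordinates, got '", lines[i + j], "'")
      coords[j, ] <- vals
    }
    i <- i + k + 1L
    id <- NULL; scale <- NULL
    # trailing keyword records for this specimen
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^LM3?\\s*=", ln, ignore.case = TRUE)) break
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE\\s*=\\s*", "", ln,
                                                 ignore.case = TRUE)))
        if (is.na(scale)) stop("TPS parse error at line ", i, ": bad SCALE value")
      } else if (grepl("^(CURVES|POINTS)\\s*=", ln, ignore.case = TRUE)) {
        warning("TPS curve/semilandmark records skipped at line ", i)
      } else if (grepl("^[A-Za-z]+\\s*=", ln)) {
        # unknown keyword record (IMAGE=, COMMENT=...): ignore
      } else stop("TPS parse error at line ", i, ": unexpected '", ln, "'")
      i <- i + 1L
    }
    nrec <- nrec + 1L
    if (!is.null(scale)) coords <- coords * scale
    configs[[nrec]] <- landmark_config(
      coords, specimen_id = if (is.null(id)) paste0("specimen", nrec) else id)
  }
  if (!nrec) stop("no landmark records found in ", path)
  landmark_sample(configs)
}

read_landmarks_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(df))
    stop("CSV parse error: leading 'specimen_id' column required in ", path)
  ids <- as.character(df$specimen_id)
  cc <- setdiff(names(df), "specimen_id")
  base <- sub("_(x|y|z)$", "", cc)
  axis <- sub("^.*_(x|y|z)$", "\\1", cc)
  if (any(base == cc)) stop("CSV parse error: coordinate columns must end in _x/_y/_z")
  labels <- unique(base)
  d <- length(unique(axis))
  axes <- c("x", "y", "z")[seq_len(d)]
  for (lb in labels) for (a in axes)
    if (!paste0(lb, "_", a) %in% cc)
      stop("CSV parse error: missing column ", lb, "_", a)
  configs <- lapply(seq_len(nrow(df)), function(i) {
    coords <- sapply(axes, function(a)
      as.numeric(df[i, paste0(labels, "_", a)]))
    landmark_config(matrix(coords, ncol = d), labels = labels,
                    specimen_id = ids[i])
  })
  landmark_sample(configs, specimen_ids = ids)
}

#' Write landmark data to a TPS or CSV file
#'
#' Coordinates are written with 15 significant digits so the
#' write/read round trip is the identity to well below 1e-12.
#'
#' @param sample a [landmark_sample()].
#' @param path output file path.
#' @param format `"tps"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sample, path, format = c("auto", "tps", "csv")) {
  stopifnot(inherits(sample, "landmark_sample"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tps"
  if (length(sample) < 1) stop("cannot write an empty sample (n >= 1 required)")
  k <- n_landmarks(sample); d <- n_dim(sample)
  if (format == "tps") {
    lines <- character(0)
    for (i in seq_len(length(sample))) {
      lines <- c(lines,
                 paste0(if (d == 3) "LM3=" else "LM=", k),
                 apply(sample$coords[, , i, drop = FALSE], 1,
                       function(r) paste(formatC(r, digits = 15, format = "g"),
                                         collapse = " ")),
                 paste0("ID=", sample$specimen_ids[i]))
    }
    writeLines(lines, path)
  } else {
    axes <- c("x", "y", "z")[seq_len(d)]
    wide <- t(apply(sample$coords, 3, function(m) as.vector(t(m))))
    colnames(wide) <- as.vector(t(outer(sample$labels, axes, paste, sep = "_")))
    df <- data.frame(specimen_id = sample$specimen_ids, wide,
                     check.names = FALSE)
    write.csv(format(df, digits = 15, trim = TRUE), path, row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}

# ---- trees and matrices -----------------------------------------------------

#' Read a rooted, fully bifurcating phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()].  Branch lengths must be
#' present and strictly positive on all edges; polytomies are rejected
#' because the contrast machinery gives no rule for resolving them.
#'
#' @param path Newick file path (or a Newick string via `text`).
#' @param text optional Newick string, used instead of `path`.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("Newick parse error")
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (length(tr$edge.length) != nrow(tr$edge) || any(is.na(tr$edge.length)))
    stop("every edge needs a branch length")
  if (any(tr$edge.length <= 0)) stop("branch lengths must be strictly positive")
  if (!ape::is.binary(tr)) stop("tree has polytomies; contrasts need a fully bifurcating tree")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  if (anyDuplicated(tr$tip.label)) stop("duplicated tip names")
  tr
}

#' Read a symmetric matrix from square CSV
#'
#' Expects a header row and a leading name column; checks symmetry and, for
#' `kind = "correlation"`, a unit diagonal.
#'
#' @param path CSV path.
#' @param kind `"correlation"` or `"covariance"`.
#' @param tol symmetry tolerance.
#' @return symmetric numeric matrix with dimnames, attribute `kind`.
#' @export
read_square_matrix <- function(path, kind = c("correlation", "covariance"),
                               tol = 1e-8) {
  kind <- match.arg(kind)
  df <- read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (max(abs(m - t(m))) > tol) stop("matrix in ", path, " is not symmetric")
  m <- (m + t(m)) / 2
  if (kind == "correlation" && max(abs(diag(m) - 1)) > tol)
    stop("correlation matrix must have a unit diagonal")
  attr(m, "kind") <- kind
  m
}
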