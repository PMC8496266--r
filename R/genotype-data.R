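#' Genotype container
#'
#' Bundles an individuals-by-markers dosage matrix (coded 0/1/2, the count of
#' one allele) with a physical marker map. Markers are stored sorted by
#' chromosome and base-pair position; dosages outside \{0,1,2\} and missing
#' values are rejected.
#'
#' @param X numeric matrix, individuals in rows, markers in columns, entries
#'   in \{0,1,2\}.
#' @param map data frame with columns `marker_id`, `chrom`, `pos_bp`
#'   (non-negative base-pair positions), one row per column of `X`.
#' @param ids character vector of individual identifiers (defaults to the row
#'   names of `X`, or `ind1..n`).
#' @return An object of class `genotype_data`: a list with elements `X`
#'   (dosage matrix with dimnames), `map`, and `ids`.
#' @export
genotype_data <- function(X, map, ids = rownames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(X)))
  ids <- as.character(ids)
  if (length(ids) != nrow(X)) stop("length(ids) must equal nrow(X)")
  if (!is.data.frame(map)) stop("map must be a data frame")
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(map)))
    stop("map must have columns marker_id, chrom, pos_bp")
  map <- data.frame(marker_id = as.character(map$marker_id),
                    chrom = as.character(map$chrom),
                    pos_bp = as.numeric(map$pos_bp),
                    stringsAsFactors = FALSE)
  if (nrow(map) != ncol(X))
    stop("map has ", nrow(map), " rows but X has ", ncol(X), " markers")
  if (anyNA(map$pos_bp) || any(map$pos_bp < 0))
    stop("pos_bp must be non-negative")
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing dosage at individual %d, marker %d", idx[1L], idx[2L]))
  }
  bad <- which(X != 0 & X != 1 & X != 2, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("dosage %s not in {0,1,2} at row %d (individual '%s'), column %d (marker '%s')",
                 format(X[i, j]), i, ids[i], j, map$marker_id[j]))
  }
  o <- order(map$chrom, map$pos_bp)
  X <- X[, o, drop = FALSE]
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  dimnames(X) <- list(ids, map$marker_id)
  structure(list(X = X, map = map, ids = ids), class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$X), "individuals x", ncol(x$X), "markers on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$X)

as_dosage_matrix <- function(geno) {
  if (inherits(geno, "genotype_data")) geno$X else as.matrix(geno)
}

#' Read a genotype file with its marker map
#'
#' Supports two dialects: `csv` (header of marker ids, first column individual
#' ids) and `plink_raw` (whitespace-separated additive dosage export: header
#' row, six leading non-genotype columns FID/IID/PAT/MAT/SEX/PHENOTYPE, marker
#' columns named `<marker>_<allele>`). The map file is a CSV with columns
#' `marker_id`, `chrom`, `pos_bp`. Markers are sorted by (chrom, pos_bp) and
#' monomorphic markers are dropped with a warning. Missing dosages are an
#' error unless `missing = "mode"`, which imputes the per-marker modal dosage.
#'
#' @param path genotype file.
#' @param map_path marker map CSV.
#' @param format `"csv"` or `"plink_raw"`.
#' @param missing `"error"` (default) or `"mode"`.
#' @param drop_monomorphic drop zero-variance markers (default `TRUE`).
#' @return A [genotype_data] object.
#' @export
read_genotypes <- function(path, map_path, format = c("csv", "plink_raw"),
                           missing = c("error", "mode"),
                           drop_monomorphic = TRUE) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  sep <- if (format == "csv") "," else ""
  nf <- utils::count.fields(path, sep = sep)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("malformed genotype file: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]))
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2L) stop("csv genotype file needs an id column plus markers")
    ids <- as.character(raw[[1L]])
    X <- as.matrix(raw[, -1L, drop = FALSE])
  } else {
    raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 7L)
      stop("plink_raw file must have 6 leading columns plus dosage columns")
    ids <- as.character(raw[[2L]])
    X <- as.matrix(raw[, -(1:6), drop = FALSE])
    colnames(X) <- sub("_[A-Za-z0-9]+$", "", colnames(X))
  }
  storage.mode(X) <- "double"
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "chrom", "pos_bp") %in% names(map)))
    stop("map file must have columns marker_id, chrom, pos_bp")
  map$marker_id <- as.character(map$marker_id)
  if (!setequal(colnames(X), map$marker_id))
    stop("marker ids in the map do not match the genotype columns")
  X <- X[, map$marker_id, drop = FALSE]

  if (anyNA(X)) {
    all_missing <- colSums(!is.na(X)) == 0L
    if (any(all_missing))
      stop("marker(s) with all dosages missing: ",
           paste(colnames(X)[all_missing], collapse = ", "))
    if (missing == "error") {
      idx <- which(is.na(X), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing dosage at row %d, marker '%s' (use missing = \"mode\" to impute)",
                   idx[1L], colnames(X)[idx[2L]]))
    }
    for (j in which(colSums(is.na(X)) > 0L)) {
      tab <- table(X[, j])
      X[is.na(X[, j]), j] <- as.numeric(names(tab)[which.max(tab)])
    }
  }
  bad <- which(X != 0 & X != 1 & X != 2, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("invalid dosage %s at row %d, column '%s'",
                 format(X[i, j]), i, colnames(X)[j]))
  }
  geno <- genotype_data(X, map, ids)
  if (drop_monomorphic) {
    v <- apply(geno$X, 2L, stats::var)
    mono <- v == 0
    if (any(mono)) {
      warning(sprintf("dropped %d monomorphic marker(s)", sum(mono)))
      geno$X <- geno$X[, !mono, drop = FALSE]
      geno$map <- geno$map[!mono, , drop = FALSE]
      rownames(geno$map) <- NULL
    }
  }
  geno
}

#' Write genotypes and map as CSV
#'
#' Inverse of [read_genotypes()] for the `csv` dialect; a read after a write
#' reproduces the dosage matrix, ids and map exactly.
#'
#' @param geno a [genotype_data] object.
#' @param path,map_path output files.
#' @export
write_genotypes <- function(geno, path, map_path) {
  df <- data.frame(id = geno$ids, geno$X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(geno$map, map_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with the individual id in the first column and the phenotype in the
#' second.
#'
#' @param path phenotype CSV.
#' @return data frame with columns `id` and `y`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("phenotype file needs id and value columns")
  out <- data.frame(id = as.character(raw[[1L]]), y = as.numeric(raw[[2L]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$y) || any(!is.finite(out$y)))
    stop("phenotypes must be finite")
  out
}

# align a phenotype table (or named/plain vector) to the genotype ids
align_trait <- function(geno, trait) {
  if (is.data.frame(trait)) {
    idx <- match(geno$ids, as.character(trait[[1L]]))
    if (anyNA(idx))
      stop("phenotypes missing for individual(s): ",
           paste(utils::head(geno$ids[is.na(idx)], 5L), collapse = ", "))
    y <- as.numeric(trait[[2L]][idx])
  } else {
    y <- as.numeric(trait)
    if (length(y) != length(geno$ids))
      stop("phenotype length does not match the number of individuals")
  }
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  y
}

#' Non-overlapping genomic windows
#'
#' Partitions the markers of a [genotype_data] into consecutive half-open
#' physical windows `[k*window_bp, (k+1)*window_bp)` per chromosome. Windows
#' containing no marker are omitted, so the marker lists partition the marker
#' set.
#'
#' @param geno a [genotype_data] object.
#' @param window_bp window width in base pairs (default 1 Mb).
#' @return An object of class `window_set`: list with `windows` (data frame
#'   `window_id`, `chrom`, `bin`, `start_bp`, `end_bp`, `n_markers`),
#'   `markers` (list of marker index vectors), and `window_bp`. `bin` is the
#'   0-based window index within its chromosome.
#' @export
genome_windows <- function(geno, window_bp = 1e6) {
  if (!is.numeric(window_bp) || length(window_bp) != 1L || window_bp <= 0)
    stop("window_bp must be a positive number")
  map <- geno$map
  bin <- floor(map$pos_bp / window_bp)
  key <- paste(map$chrom, bin, sep = ":")
  keyf <- factor(key, levels = unique(key))
  idx <- split(seq_len(nrow(map)), keyf)
  first <- vapply(idx, `[[`, integer(1L), 1L)
  meta <- data.frame(window_id = seq_along(idx),
                     chrom = map$chrom[first],
                     bin = bin[first],
                     start_bp = bin[first] * window_bp,
                     end_bp = (bin[first] + 1) * window_bp,
                     n_markers = lengths(idx),
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  structure(list(windows = meta, markers = unname(idx), window_bp = window_bp),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set:", nrow(x$windows), "windows of", format(x$window_bp),
      "bp covering", sum(x$windows$n_markers), "markers\n")
  invisible(x)
}

#' Export windows as BED-like text
#'
#' Tab-separated columns: chrom, start, end, n_markers, window_id (no header).
#'
#' @param windows a `window_set`.
#' @param path output file.
#' @export
write_windows_bed <- function(windows, path) {
  w <- windows$windows
  utils::write.table(w[, c("chrom", "start_bp", "end_bp", "n_markers", "window_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Random train/validation split
#'
#' @param n number of observations.
#' @param fraction_train fraction used for training; the training size is
#'   `round(fraction_train * n)`.
#' @param seed optional integer seed (calls `set.seed`).
#' @return list with sorted integer vectors `train` and `validation`, a
#'   partition of `1..n`.
#' @export
split_train_validation <- function(n, fraction_train = 0.8, seed = NULL) {
  if (n < 2) stop("need at least 2 observations")
  if (fraction_train <= 0 || fraction_train >= 1)
    stop("fraction_train must be in (0, 1)")
  k <- round(fraction_train * n)
  if (k == 0 || k == n)
    stop("fraction_train produces an empty train or validation set")
  if (!is.null(seed)) set.seed(seed)
  train <- sort(sample.int(n, k))
  list(train = train, validation = setdiff(seq_len(n), train))
}
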