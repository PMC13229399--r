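# TSV-based file formats: labeled numeric matrices (samples x variables),
# two-column cis maps, edge lists, benchmark reports, and flat key/value
# design configs.  All indices in files are 1-based ids; conversion to
# internal representations happens only here.

#' Read a labeled numeric matrix from TSV
#'
#' Expects a rectangular tab-separated file with a header row of variable
#' ids and a first column of sample ids.  Ragged rows, non-numeric or
#' missing cells, and duplicate ids are rejected with the offending line
#' named.
#'
#' @param path file path.
#' @param orientation `"samples_by_variables"` (default) or
#'   `"variables_by_samples"` (the file is transposed after reading).
#' @return numeric matrix with row and column names.
#' @export
readMatrixTSV <- function(path,
                          orientation = c("samples_by_variables",
                                          "variables_by_samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]][-1L]
  ncols <- length(fields[[1L]])
  if (anyDuplicated(header))
    stop("duplicate column ids in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  body <- fields[-1L]
  rows <- length(body)
  bad <- which(lengths(body) != ncols)
  if (length(bad))
    stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                 bad[1L] + 1L, path, lengths(body)[bad[1L]], ncols))
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  M <- matrix(NA_real_, rows, ncols - 1L, dimnames = list(ids, header))
  for (i in seq_len(rows)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf(
        "non-numeric or missing cell at line %d (row '%s', column '%s') of %s: '%s'",
        i + 1L, ids[i], header[j], path, body[[i]][j + 1L]))
    }
    M[i, ] <- v
  }
  if (orientation == "variables_by_samples") M <- t(M)
  M
}

#' Write a labeled numeric matrix to TSV
#'
#' Inverse of [readMatrixTSV()]: header row of column ids, first column of
#' row ids, tab-separated, full double precision.
#'
#' @param M numeric matrix with dimnames (defaults generated if absent).
#' @param path output path.
#' @param idHeader label for the id column (first header field).
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(M, path, idHeader = "id") {
  M <- as.matrix(M)
  if (is.null(rownames(M))) rownames(M) <- paste0("S", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("V", seq_len(ncol(M)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(idHeader, colnames(M)), collapse = "\t"), con)
  body <- apply(M, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(M), body, sep = "\t"), con)
  invisible(path)
}

#' Read a cis map from a two-column TSV
#'
#' The file has a header and two columns, `gene_id` and `marker_id`, with
#' possibly several rows per gene.  Ids must exist in the supplied label
#' vectors.  Duplicated (gene, marker) rows are deduplicated with a
#' warning; a marker assigned to two genes violates the identifiability
#' assumption and is a hard error, as is a gene with no markers.
#'
#' @param path file path.
#' @param geneIds,markerIds label vectors defining the index spaces.
#' @return a validated [CisMap-class].
#' @export
readCisMapTSV <- function(path, geneIds, markerIds) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("cis map file must have two columns (gene_id, marker_id): ", path)
  g <- tab[[1L]]; m <- tab[[2L]]
  unknownG <- setdiff(unique(g), geneIds)
  if (length(unknownG))
    stop("unknown gene id(s) in ", path, ": ",
         paste(unknownG, collapse = ", "))
  unknownM <- setdiff(unique(m), markerIds)
  if (length(unknownM))
    stop("unknown marker id(s) in ", path, ": ",
         paste(unknownM, collapse = ", "))
  dup <- duplicated(paste(g, m, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicated (gene, marker) row(s) dropped")
    g <- g[!dup]; m <- m[!dup]
  }
  mi <- match(m, markerIds)
  owners <- tapply(match(g, geneIds), mi, unique)
  multi <- names(owners)[lengths(owners) > 1L]
  if (length(multi))
    stop("marker(s) assigned to more than one gene (violates the unique-cis assumption): ",
         paste(markerIds[as.integer(multi)], collapse = ", "))
  sets <- lapply(geneIds, function(id) sort(mi[g == id]))
  missing <- geneIds[lengths(sets) == 0L]
  if (length(missing))
    stop("gene(s) without any cis marker: ", paste(missing, collapse = ", "))
  cisMap(sets, q = length(markerIds))
}

#' Write a cis map to a two-column TSV
#'
#' @param cis a [CisMap-class].
#' @param path output path.
#' @param geneIds,markerIds label vectors (defaults `G1..`, `M1..`).
#' @return `path`, invisibly.
#' @export
writeCisMapTSV <- function(cis, path, geneIds = NULL, markerIds = NULL) {
  stopifnot(is(cis, "CisMap"))
  p <- length(cis@sets)
  if (is.null(geneIds)) geneIds <- paste0("G", seq_len(p))
  if (is.null(markerIds)) markerIds <- paste0("M", seq_len(cis@q))
  rows <- do.call(rbind, lapply(seq_len(p), function(k)
    data.frame(gene_id = geneIds[k], marker_id = markerIds[cis@sets[[k]]])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an estimated network (optionally bootstrap-annotated) as an edge list
#'
#' One row per directed edge, sorted by target then by decreasing
#' `|gamma_hat|`, with columns `regulator`, `target`, `gamma_hat`,
#' `bootstrap_freq` (empty when no bootstrap summary is supplied) and
#' `method`.  When bootstrap frequencies are present, rows below
#' `freqThreshold` are filtered out, so the 0.95-threshold file is a
#' subset of the 0.80 one.
#'
#' @param estimate a [NetworkEstimate-class].
#' @param path output path.
#' @param bootstrap optional [BootstrapSummary-class] from the same data.
#' @param freqThreshold minimum bootstrap frequency to keep an edge
#'   (ignored without `bootstrap`).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(estimate, path, bootstrap = NULL,
                          freqThreshold = 0) {
  stopifnot(is(estimate, "NetworkEstimate"))
  G <- estimate@GammaHat
  ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("G", seq_len(nrow(G)))
  idx <- which(abs(G) > 0, arr.ind = TRUE)
  tab <- data.frame(regulator = ids[idx[, 1L]], target = ids[idx[, 2L]],
                    gamma_hat = G[idx],
                    bootstrap_freq = rep(NA_real_, nrow(idx)),
                    method = rep(estimate@method, nrow(idx)))
  if (!is.null(bootstrap)) {
    stopifnot(is(bootstrap, "BootstrapSummary"))
    tab$bootstrap_freq <- bootstrap@freq[idx]
    tab <- tab[tab$bootstrap_freq >= freqThreshold, , drop = FALSE]
  }
  tab <- tab[order(tab$target, -abs(tab$gamma_hat)), , drop = FALSE]
  utils::write.table(format(tab, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [writeEdgeList()]
#'
#' @param path file path.
#' @return data.frame with columns `regulator`, `target`, `gamma_hat`,
#'   `bootstrap_freq`, `method`.
#' @export
readEdgeList <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "numeric", "numeric", "character"))
  tab
}

#' Read/write a simulation design as a flat key/value config file
#'
#' The config mirrors [simulationDesign()]'s arguments one key per line
#' (YAML scalar syntax, e.g. `p: 300`).  Unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path file path.
#' @return a [SimulationDesign-class].
#' @export
readDesignConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(simulationDesign))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown design key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(simulationDesign, vals)
}

#' @rdname readDesignConfig
#' @param design a [SimulationDesign-class].
#' @return `path`, invisibly.
#' @export
writeDesignConfig <- function(design, path) {
  stopifnot(is(design, "SimulationDesign"))
  vals <- list(p = design@p, n = design@n, topology = design@topology,
               edgeMean = design@edgeMean, eePerGene = design@eePerGene,
               errorModel = design@errorModel, errorSD = design@errorSD,
               hubCount = design@hubCount, hubEdgeMean = design@hubEdgeMean,
               correlatedEE = design@correlatedEE)
  yaml::write_yaml(vals, path)
  invisible(path)
}
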