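# Readers and writers for the external table dialects. All readers validate
# strictly and return the package's S4 domain objects; all writers produce
# deterministic, tab-separated plain text so that identical inputs give
# byte-identical files.

.readDelimited <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read and aggregate per-study differential-miRNA lists
#'
#' Pools per-study lists of differentially expressed circulating miRNAs into
#' a single signature, regardless of fold change or measurement
#' circumstances, noting only the direction. Each file is a two-column table
#' (header \code{mirna_id}, \code{direction}) tagged with a study identifier
#' taken from the names of \code{files} (or the file base name). The same
#' miRNA reported \code{high} in one study and \code{low} in another is a
#' hard input error, not a tie to resolve.
#'
#' @param files character vector of file paths; names (if any) are used as
#'   study identifiers.
#' @param merge if \code{TRUE} (default) return one aggregated
#'   [MiRNASignature-class]; otherwise a named list of per-study signatures.
#' @return A [MiRNASignature-class], or a list of them when
#'   \code{merge = FALSE}.
#' @examples
#' f <- tempfile(); writeLines(c("mirna_id\tdirection",
#'                               "hsa-miR-21-5p\thigh"), f)
#' readSignatureLists(c(studyA = f))
#' @export
readSignatureLists <- function(files, merge = TRUE) {
  if (length(files) == 0L) stop("no signature files given", call. = FALSE)
  studies <- names(files)
  if (is.null(studies) || any(!nzchar(studies)))
    studies <- tools::file_path_sans_ext(basename(files))
  perStudy <- lapply(seq_along(files), function(i) {
    d <- .readDelimited(files[[i]])
    if (!all(c("mirna_id", "direction") %in% names(d)))
      stop("signature file ", files[[i]],
           " needs columns 'mirna_id' and 'direction'", call. = FALSE)
    if (nrow(d) == 0L)
      stop("signature file ", files[[i]], " is empty", call. = FALSE)
    if (!all(d$direction %in% .DIRECTIONS))
      stop("invalid direction token in ", files[[i]], call. = FALSE)
    MiRNASignature(d$mirna_id, d$direction, studies[[i]])
  })
  names(perStudy) <- studies
  if (!merge) return(perStudy)
  mirna <- character(); dir <- character(); src <- list()
  keyOf <- function(x) tolower(trimws(x))
  for (i in seq_along(perStudy)) {
    s <- perStudy[[i]]
    for (j in seq_along(s@mirna)) {
      key <- keyOf(s@mirna[j])
      hit <- match(key, keyOf(mirna))
      if (is.na(hit)) {
        mirna <- c(mirna, s@mirna[j])
        dir <- c(dir, s@direction[j])
        src <- c(src, list(studies[[i]]))
      } else {
        if (dir[hit] != s@direction[j])
          stop("conflicting directions across studies for miRNA ",
               s@mirna[j], call. = FALSE)
        src[[hit]] <- union(src[[hit]], studies[[i]])
      }
    }
  }
  MiRNASignature(mirna, dir, src)
}

#' Serialize / deserialize an aggregated signature
#'
#' Single-file round-trip format: tab-separated with columns
#' \code{mirna_id}, \code{direction}, \code{sources} (semicolon-joined study
#' tags), rows sorted by identifier.
#'
#' @param signature a [MiRNASignature-class].
#' @param path file path.
#' @return \code{writeSignature}: \code{path}, invisibly;
#'   \code{readSignature}: a [MiRNASignature-class].
#' @export
writeSignature <- function(signature, path) {
  ord <- order(signature@mirna)
  d <- data.frame(mirna_id = signature@mirna[ord],
                  direction = signature@direction[ord],
                  sources = vapply(signature@sources[ord],
                                   function(s) paste(sort(s), collapse = ";"),
                                   character(1)),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  d <- .readDelimited(path, sep = "\t")
  if (!all(c("mirna_id", "direction", "sources") %in% names(d)))
    stop("signature file needs columns mirna_id, direction, sources",
         call. = FALSE)
  MiRNASignature(d$mirna_id, d$direction,
                 strsplit(as.character(d$sources), ";", fixed = TRUE))
}

#' Read a miRNA-target interaction (MTI) table
#'
#' Parses the MTI dialect (tab- or comma-separated, header row, one evidence
#' record per row) and reduces it to unique (miRNA, gene) pairs for the
#' requested species. Required columns: \code{miRNA},
#' \code{Species (miRNA)}, \code{Target Gene}, \code{Species (Target Gene)};
#' extra columns (support type, PMIDs, ...) are ignored. Rows must match the
#' species on both the miRNA and the gene side to survive the filter. No
#' evidence-strength filtering is applied.
#'
#' @param path file path.
#' @param species organism tag, default \code{"Homo sapiens"}.
#' @return A [TargetInteractionTable-class]; \code{rawRecordCount()} reports
#'   the species-matched record count before pair deduplication.
#' @export
readMtiTable <- function(path, species = "Homo sapiens") {
  d <- .readDelimited(path)
  need <- c("miRNA", "Species (miRNA)", "Target Gene",
            "Species (Target Gene)")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("MTI table is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- d[["Species (miRNA)"]] == species &
    d[["Species (Target Gene)"]] == species
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no MTI records left after filtering to species '", species, "'",
         call. = FALSE)
  TargetInteractionTable(d[["miRNA"]], d[["Target Gene"]],
                         speciesFilter = species,
                         recordCountRaw = nrow(d))
}

#' Write a TargetInteractionTable in the MTI dialect
#'
#' One row per unique pair (evidence multiplicity is not reconstructed),
#' sorted by (miRNA, gene), with the species columns filled from the table's
#' species filter.
#'
#' @param mti a [TargetInteractionTable-class].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeMtiTable <- function(mti, path) {
  p <- mti@pairs[order(mti@pairs$mirna, mti@pairs$gene), , drop = FALSE]
  d <- data.frame(miRNA = p$mirna,
                  `Species (miRNA)` = mti@speciesFilter,
                  `Target Gene` = p$gene,
                  `Species (Target Gene)` = mti@speciesFilter,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Whitespace- or tab-separated three-column edge list (\code{protein_a},
#' \code{protein_b}, \code{combined_score}) with a header row. Scores on the
#' source dialect's 0-1000 integer scale are divided by 1000; pairs are
#' canonicalized (duplicates keep the maximum confidence) and self-loops are
#' dropped with a message. A score outside the declared scale is a hard
#' error.
#'
#' @param path file path.
#' @param scoreScale \code{"0-1000"} (default) or \code{"0-1"}.
#' @return An [UndirectedPPINetwork-class].
#' @export
readPpiNetwork <- function(path, scoreScale = c("0-1000", "0-1")) {
  scoreScale <- match.arg(scoreScale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 3L)
    stop("PPI edge list needs three columns", call. = FALSE)
  score <- as.numeric(d[[3]])
  hi <- if (scoreScale == "0-1000") 1000 else 1
  if (any(is.na(score)) || any(score < 0 | score > hi))
    stop("combined score outside declared scale ", scoreScale, call. = FALSE)
  conf <- score / hi
  self <- d[[1]] == d[[2]]
  if (any(self))
    message("dropping ", sum(self), " self-loop(s) from PPI input")
  UndirectedPPINetwork(d[[1]][!self], d[[2]][!self], conf[!self])
}

#' Write an UndirectedPPINetwork
#'
#' Canonical 3-column edge list; confidences are written on the 0-1 scale.
#'
#' @param ppi an [UndirectedPPINetwork-class].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writePpiNetwork <- function(ppi, path) {
  e <- ppi@edges
  d <- data.frame(protein_a = e$geneA, protein_b = e$geneB,
                  combined_score = e$confidence, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed signed interaction network
#'
#' Tab-separated with header \code{source}, \code{target}, \code{direction},
#' \code{sign}, \code{provenance}. Direction markers \code{both} and
#' \code{undirected} are preserved for [trimToDirected()]. Unknown direction
#' or sign tokens are a hard error reporting the offending line.
#'
#' @param path file path.
#' @return A [DirectedInteractionNetwork-class].
#' @export
readDirectedNetwork <- function(path) {
  d <- .readDelimited(path, sep = "\t")
  need <- c("source", "target", "direction", "sign", "provenance")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("directed network file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  badDir <- which(!(d$direction %in% .EDGE_DIRECTIONS))
  if (length(badDir))
    stop("unknown direction token '", d$direction[badDir[1]],
         "' at data line ", badDir[1], call. = FALSE)
  badSign <- which(!(d$sign %in% .SIGNS))
  if (length(badSign))
    stop("unknown sign token '", d$sign[badSign[1]], "' at data line ",
         badSign[1], call. = FALSE)
  DirectedInteractionNetwork(d$source, d$target, d$direction, d$sign,
                             d$provenance)
}

#' Write a DirectedInteractionNetwork
#'
#' @param net a [DirectedInteractionNetwork-class].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeDirectedNetwork <- function(net, path) {
  e <- net@edges[order(net@edges$source, net@edges$target), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a manual-annotation table
#'
#' Tab-separated with header \code{gene_a}, \code{gene_b},
#' \code{resolved_direction} (\code{a_to_b}/\code{b_to_a}/\code{both}/
#' \code{none}), \code{sign}, \code{provenance}; one row per unordered pair.
#'
#' @param path file path.
#' @return An [AnnotationTable-class].
#' @export
readAnnotationTable <- function(path) {
  d <- .readDelimited(path, sep = "\t")
  need <- c("gene_a", "gene_b", "resolved_direction", "sign", "provenance")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("annotation table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  AnnotationTable(d$gene_a, d$gene_b, d$resolved_direction, d$sign,
                  d$provenance)
}

#' Write result tables and a machine-readable run summary
#'
#' Writes every recognized result object in \code{tables} as a
#' deterministic, tab-separated file under \code{outDir}
#' (\code{gene_scores.tsv}, \code{centrality.tsv}, \code{influence.tsv},
#' \code{null_sums.tsv}, \code{null_edges_<thr>.tsv}) plus a JSON
#' \code{run_summary.json} recording parameters, seed and counts. Identical
#' inputs give byte-identical files.
#'
#' @param tables named or unnamed list of [GeneScoreTable-class],
#'   [CentralityTable-class], [PermutationResult-class] and/or
#'   [InfluenceResult-class] objects.
#' @param outDir output directory, created if needed.
#' @param extra named list merged into the run summary (e.g. pipeline
#'   parameters).
#' @return invisible character vector of written paths.
#' @export
writeResults <- function(tables, outDir, extra = list()) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory ", outDir, call. = FALSE)
  probe <- file.path(outDir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("output directory not writable: ", outDir, call. = FALSE)
  unlink(probe)
  written <- character()
  summary <- extra
  writeTsv <- function(d, file) {
    utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, file)
  }
  for (x in tables) {
    if (is(x, "GeneScoreTable")) {
      writeTsv(x@scores, file.path(outDir, "gene_scores.tsv"))
      summary$n_scored_genes <- nrow(x@scores)
    } else if (is(x, "CentralityTable")) {
      writeTsv(x@scores, file.path(outDir, "centrality.tsv"))
      summary$katz_alpha <- x@alpha
      summary$katz_beta <- x@beta
      summary$n_centrality_genes <- nrow(x@scores)
    } else if (is(x, "InfluenceResult")) {
      writeTsv(x@scores, file.path(outDir, "influence.tsv"))
      summary$influence_alpha <- x@alpha
      summary$max_path_len <- x@maxPathLen
    } else if (is(x, "PermutationResult")) {
      writeTsv(data.frame(null_sum = x@nullSums),
               file.path(outDir, "null_sums.tsv"))
      for (th in names(x@nullEdges))
        writeTsv(data.frame(null_edges = x@nullEdges[[th]]),
                 file.path(outDir, paste0("null_edges_", th, ".tsv")))
      summary$n_iter <- x@nIter
      summary$top_k <- x@k
      summary$seed <- x@seed
      summary$observed_sum <- x@observedSum
      summary$observed_edges <- as.list(x@observedEdges)
      summary$p_strict <- list(sum = x@pStrict$sum,
                               edges = as.list(x@pStrict$edges))
      summary$p_addone <- list(sum = x@pAddone$sum,
                               edges = as.list(x@pAddone$edges))
    } else {
      stop("writeResults does not know how to serialize an object of class ",
           class(x)[1], call. = FALSE)
    }
  }
  summaryPath <- file.path(outDir, "run_summary.json")
  jsonlite::write_json(summary, summaryPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, summaryPath)
  invisible(written)
}
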