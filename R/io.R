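## genome_io: FASTA / AGP / PAF / marker-table readers and writers, plus the
## AGP tiling validator used throughout the tests.

#' Read a FASTA file into a DNAStringSet
#'
#' Bases are upper-cased, `U` is mapped to `T`, and any other IUPAC
#' ambiguity code is degraded to `N` (with a warning) so that real
#' assemblies can be ingested. Sequence ids are the first whitespace-token
#' of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtn"), f)
#' readFastaRecords(f)
readFastaRecords <- function(path) {
    stopifnot(file.exists(path))
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) {
        warning("FASTA file '", path, "' contains no sequences")
        return(Biostrings::DNAStringSet())
    }
    ids <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(ids)) {
        dup <- unique(ids[duplicated(ids)])
        stop("duplicate sequence id(s) in '", path, "': ",
             paste(dup, collapse = ", "))
    }
    seqs <- toupper(as.character(x))
    seqs <- chartr("U", "T", seqs)
    bad <- gsub("[ACGTN]", "", seqs)
    if (any(nchar(bad) > 0L)) {
        warning("non-ACGTN IUPAC code(s) [",
                paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
                      collapse = ""),
                "] mapped to N")
        seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "",
                       USE.NAMES = FALSE)
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Write sequences to FASTA
#'
#' @param x a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @param width line-wrap width, default 80.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(x, path, width = 80L) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path, width = width)
    invisible(path)
}

#' Validate AGP component tiling
#'
#' Checks the AGP invariants: within each object, components sorted by
#' `object_start` tile `1..object_end` without gap or overlap, and contig
#' components have matching object/component widths.
#'
#' @param components data.frame with columns `object_id`, `object_start`,
#'   `object_end` (1-based inclusive), `component_type` (`"contig"` or
#'   `"gap"`), `component_id`, `component_start`, `component_end`,
#'   `orientation` (`+`, `-`, `?`).
#' @return `TRUE` invisibly, or an error naming the offending rows.
#' @export
validateAgp <- function(components) {
    if (nrow(components) == 0L) return(invisible(TRUE))
    bad <- integer()
    for (obj in unique(components$object_id)) {
        rows <- which(components$object_id == obj)
        sub <- components[rows, , drop = FALSE]
        if (is.unsorted(sub$object_start, strictly = TRUE)) {
            bad <- c(bad, rows)
            next
        }
        expected <- c(1, sub$object_end[-nrow(sub)] + 1)
        bad <- c(bad, rows[sub$object_start != expected])
        bad <- c(bad, rows[sub$object_end < sub$object_start])
        ctg <- sub$component_type == "contig"
        wmis <- ctg & (sub$component_end - sub$component_start !=
                       sub$object_end - sub$object_start)
        bad <- c(bad, rows[wmis])
    }
    bad <- sort(unique(bad))
    if (length(bad))
        stop("AGP tiling violation at row(s): ", paste(bad, collapse = ", "))
    invisible(TRUE)
}

#' Write an AGP v2.1 file
#'
#' Gap rows are emitted as component type `N` with the gap length,
#' `scaffold`, `yes`, `map` in columns 6--9.
#'
#' @inheritParams validateAgp
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAgp <- function(components, path) {
    if (nrow(components) == 0L) {
        warning("writing empty AGP file")
        file.create(path)
        return(invisible(path))
    }
    validateAgp(components)
    lines <- character(nrow(components))
    part <- stats::ave(seq_len(nrow(components)), components$object_id,
                       FUN = seq_along)
    for (i in seq_len(nrow(components))) {
        r <- components[i, ]
        if (r$component_type == "contig") {
            lines[i] <- paste(r$object_id, r$object_start, r$object_end,
                              part[i], "W", r$component_id,
                              r$component_start, r$component_end,
                              r$orientation, sep = "\t")
        } else {
            lines[i] <- paste(r$object_id, r$object_start, r$object_end,
                              part[i], "N", r$object_end - r$object_start + 1,
                              "scaffold", "yes", "map", sep = "\t")
        }
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read an AGP file back into the component data.frame
#'
#' @param path path to an AGP file written by [writeAgp()] (comment lines
#'   starting with `#` are ignored).
#' @return data.frame in the [validateAgp()] layout.
#' @export
readAgp <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L) {
        return(data.frame(object_id = character(), object_start = numeric(),
                          object_end = numeric(), component_type = character(),
                          component_id = character(), component_start = numeric(),
                          component_end = numeric(), orientation = character(),
                          stringsAsFactors = FALSE))
    }
    f <- strsplit(lines, "\t", fixed = TRUE)
    out <- do.call(rbind, lapply(f, function(v) {
        if (v[5] %in% c("N", "U")) {
            data.frame(object_id = v[1], object_start = as.numeric(v[2]),
                       object_end = as.numeric(v[3]), component_type = "gap",
                       component_id = "", component_start = NA_real_,
                       component_end = NA_real_, orientation = "?",
                       stringsAsFactors = FALSE)
        } else {
            data.frame(object_id = v[1], object_start = as.numeric(v[2]),
                       object_end = as.numeric(v[3]), component_type = "contig",
                       component_id = v[6], component_start = as.numeric(v[7]),
                       component_end = as.numeric(v[8]), orientation = v[9],
                       stringsAsFactors = FALSE)
        }
    }))
    validateAgp(out)
    out
}

pafColumns <- c("query_id", "query_len", "query_start", "query_end",
                "strand", "target_id", "target_len", "target_start",
                "target_end", "n_matches", "block_len", "mapq")

#' Read a PAF alignment file
#'
#' The 12 mandatory minimap2 PAF columns are parsed; optional tags are
#' ignored. Rows with fewer than 12 columns are skipped with a warning (the
#' number skipped is available as `attr(x, "n_skipped")`). Coordinates are
#' 0-based half-open, as in the PAF specification.
#'
#' @param path path to a PAF file.
#' @return data.frame with the 12 mandatory columns.
#' @export
readPaf <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, 1L) < 12L
    if (any(short)) {
        warning(sum(short), " PAF row(s) with fewer than 12 columns skipped")
        fields <- fields[!short]
    }
    if (length(fields) == 0L) {
        out <- data.frame(matrix(nrow = 0, ncol = 12))
        names(out) <- pafColumns
        attr(out, "n_skipped") <- sum(short)
        return(out)
    }
    m <- do.call(rbind, lapply(fields, function(v) v[1:12]))
    out <- data.frame(
        query_id = m[, 1], query_len = as.numeric(m[, 2]),
        query_start = as.numeric(m[, 3]), query_end = as.numeric(m[, 4]),
        strand = m[, 5], target_id = m[, 6],
        target_len = as.numeric(m[, 7]), target_start = as.numeric(m[, 8]),
        target_end = as.numeric(m[, 9]), n_matches = as.numeric(m[, 10]),
        block_len = as.numeric(m[, 11]), mapq = as.integer(m[, 12]),
        stringsAsFactors = FALSE)
    if (!all(out$strand %in% c("+", "-")))
        stop("invalid PAF strand value(s): ",
             paste(unique(setdiff(out$strand, c("+", "-"))), collapse = ", "))
    bad <- which(out$query_start < 0 | out$query_start >= out$query_end |
                 out$query_end > out$query_len |
                 out$target_start < 0 | out$target_start >= out$target_end |
                 out$target_end > out$target_len |
                 out$n_matches > out$block_len)
    if (length(bad))
        stop("PAF coordinate/match invariant violated at row(s): ",
             paste(bad, collapse = ", "))
    attr(out, "n_skipped") <- sum(short)
    out
}

#' Write PAF records
#'
#' Emits the 12 mandatory columns only; tags are omitted.
#'
#' @param records data.frame as returned by [readPaf()] (a missing `mapq`
#'   column defaults to 255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePaf <- function(records, path) {
    if (is.null(records$mapq)) records$mapq <- 255L
    stopifnot(all(records$strand %in% c("+", "-")))
    lines <- apply(records[, pafColumns], 1L, function(v)
        paste(trimws(format(v, scientific = FALSE)), collapse = "\t"))
    writeLines(as.character(lines), path)
    invisible(path)
}

markerRequiredColumns <- c("marker_id", "lg", "female_cM", "male_cM",
                           "flank_left", "flank_right")

#' Read a SNP marker table
#'
#' A header-bearing TSV with at least `marker_id`, `lg`, `female_cM`,
#' `male_cM`, `flank_left`, `flank_right`. Rows are validated: cM positions
#' must be non-negative and `lg` within `1..nChromosomes`.
#'
#' @param path path to the TSV.
#' @param nChromosomes configured chromosome count (default 23).
#' @return validated data.frame of markers.
#' @export
readMarkerTable <- function(path, nChromosomes = 23L) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(markerRequiredColumns, names(tab))
    if (length(missing))
        stop("marker table '", path, "' is missing column(s): ",
             paste(missing, collapse = ", "))
    validateMarkerTable(tab, nChromosomes)
    tab
}

validateMarkerTable <- function(tab, nChromosomes = 23L) {
    badCm <- which(tab$female_cM < 0 | tab$male_cM < 0)
    if (length(badCm))
        stop("negative cM position(s) at row(s): ", paste(badCm, collapse = ", "))
    badLg <- which(tab$lg < 1L | tab$lg > nChromosomes)
    if (length(badLg))
        stop("linkage group out of range 1..", nChromosomes,
             " at row(s): ", paste(badLg, collapse = ", "))
    invisible(TRUE)
}

#' Write a SNP marker table
#'
#' @param markers data.frame of markers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMarkerTable <- function(markers, path) {
    write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
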