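## synteny_inversion: unique k-mer anchors, co-linear chaining into synteny
## blocks, inversion calling with breakpoint intervals, and the
## breakpoint-interval report. A PAF import path lets precomputed
## alignments drive the caller.

#' Find unique k-mer anchors between two genomes
#'
#' All k-mers occurring exactly once in each genome (counting both strands)
#' are matched across the genomes; maximal runs of overlapping unique
#' k-mers are merged into anchors of length >= k. Strand is `-` when the
#' target carries the reverse complement. Coordinates are 0-based
#' half-open.
#'
#' @param query,target [Biostrings::DNAStringSet]s.
#' @param k odd k-mer size (default 21).
#' @return data.frame of anchors: `q_chrom`, `q_start`, `q_end`,
#'   `t_chrom`, `t_start`, `t_end`, `strand`, `length`.
#' @export
findUniqueAnchors <- function(query, target, k = 21L) {
    stopifnot(length(query) > 0L, length(target) > 0L)
    if (k %% 2L == 0L) stop("k must be odd (palindromic k-mers have no strand)")
    df <- anchor_seeds_cpp(as.character(query), as.character(target),
                           as.integer(k))
    if (nrow(df) == 0L) {
        warning("no unique k-mer anchors found")
        return(data.frame(q_chrom = character(), q_start = numeric(),
                          q_end = numeric(), t_chrom = character(),
                          t_start = numeric(), t_end = numeric(),
                          strand = character(), length = numeric(),
                          stringsAsFactors = FALSE))
    }
    data.frame(q_chrom = names(query)[df$q_seq], q_start = df$q_start,
               q_end = df$q_start + df$length,
               t_chrom = names(target)[df$t_seq], t_start = df$t_start,
               t_end = df$t_start + df$length,
               strand = ifelse(df$strand_sign > 0, "+", "-"),
               length = df$length, stringsAsFactors = FALSE)
}

#' Chain anchors into strand-consistent synteny blocks
#'
#' Within each (query chromosome, target chromosome) pair, co-linear chains
#' are extracted best-first: the maximum-weight chain (weight = summed
#' anchor length) is found by dynamic programming, removed, and the process
#' repeats. Two anchors may be chained when they share a strand, the later
#' anchor starts after the earlier one, and both the query-side and
#' target-side gaps (start of the later minus end of the earlier, in each
#' genome's orientation of travel) lie in `[0, maxGap]`. Chains spanning
#' less than `minBlockBp` on the query or containing fewer than
#' `minAnchors` anchors are discarded.
#'
#' @param anchors data.frame from [findUniqueAnchors()].
#' @param maxGap maximum within-chain gap in bp (default 1e5).
#' @param minBlockBp minimum block span on the query in bp (default 2e4).
#' @param minAnchors minimum anchors per block (default 5).
#' @return data.frame of blocks sorted by query interval: `q_chrom`,
#'   `q_start`, `q_end`, `t_chrom`, `t_start`, `t_end`, `strand`,
#'   `n_anchors`, `span_bp`.
#' @export
chainAnchors <- function(anchors, maxGap = 1e5, minBlockBp = 2e4,
                         minAnchors = 5L) {
    blocks <- NULL
    if (nrow(anchors)) {
        grp <- paste(anchors$q_chrom, anchors$t_chrom, sep = "\r")
        for (g in unique(grp)) {
            sub <- anchors[grp == g, , drop = FALSE]
            sub <- sub[order(sub$q_start, sub$t_start), , drop = FALSE]
            remaining <- rep(TRUE, nrow(sub))
            while (any(remaining)) {
                idx <- which(remaining)
                s <- sub[idx, , drop = FALSE]
                chain <- best_chain_cpp(
                    s$q_start, s$q_end, s$t_start, s$t_end,
                    ifelse(s$strand == "+", 1L, -1L),
                    s$length, maxGap)
                sel <- idx[chain]
                cs <- sub[sel, , drop = FALSE]
                blocks <- rbind(blocks, data.frame(
                    q_chrom = cs$q_chrom[1], q_start = min(cs$q_start),
                    q_end = max(cs$q_end), t_chrom = cs$t_chrom[1],
                    t_start = min(cs$t_start), t_end = max(cs$t_end),
                    strand = cs$strand[1], n_anchors = nrow(cs),
                    span_bp = max(cs$q_end) - min(cs$q_start),
                    weight_bp = sum(cs$length),
                    stringsAsFactors = FALSE))
                remaining[sel] <- FALSE
            }
        }
    }
    if (is.null(blocks)) {
        return(data.frame(q_chrom = character(), q_start = numeric(),
                          q_end = numeric(), t_chrom = character(),
                          t_start = numeric(), t_end = numeric(),
                          strand = character(), n_anchors = integer(),
                          span_bp = numeric(), weight_bp = numeric(),
                          stringsAsFactors = FALSE))
    }
    blocks <- blocks[blocks$span_bp >= minBlockBp &
                     blocks$n_anchors >= minAnchors, , drop = FALSE]
    blocks <- blocks[order(blocks$q_chrom, blocks$q_start), , drop = FALSE]
    rownames(blocks) <- NULL
    blocks
}

#' Construct an InversionCallSet from calls and report-coordinate intervals
#'
#' `span_mb` is (re)computed per call as (last end - first start) / 1e6
#' rounded to two decimals; interval `size` as `end - start` (the
#' end-exclusive subtraction used by the breakpoint-interval report).
#'
#' @param calls data.frame with columns `call_id`, `chrom`, `kind`.
#' @param intervals data.frame with columns `call_id`, `chrom`, `start`,
#'   `end` (1-based report coordinates).
#' @return an [InversionCallSet-class].
#' @export
InversionCallSet <- function(calls, intervals) {
    intervals <- intervals[order(match(intervals$call_id, calls$call_id),
                                 intervals$start), , drop = FALSE]
    intervals$size <- intervals$end - intervals$start
    calls$span_mb <- vapply(calls$call_id, function(id) {
        sub <- intervals[intervals$call_id == id, , drop = FALSE]
        round((max(sub$end) - min(sub$start)) / 1e6, 2)
    }, 1.0)
    rownames(calls) <- rownames(intervals) <- NULL
    new("InversionCallSet", calls = calls, intervals = intervals)
}

#' @describeIn InversionCallSet accessor for the per-call table.
#' @param x an [InversionCallSet-class].
#' @export
inversionCalls <- function(x) x@calls

#' @describeIn InversionCallSet accessor for the breakpoint intervals.
#' @export
breakpointIntervals <- function(x) x@intervals

setMethod("show", "InversionCallSet", function(object) {
    cat("InversionCallSet with", nrow(object@calls), "call(s)\n")
    if (nrow(object@calls)) print(object@calls)
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@chromLengths), "chromosomes,",
        nrow(object@inversions), "planted inversion(s),",
        nrow(object@centromeres), "planted array(s),",
        nrow(object@contigs), "contig part(s),",
        nrow(object@markers), "marker(s)\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nChromosomes, "chromosomes, total",
        format(sum(object@chromLengths), big.mark = ","), "bp, seed",
        object@seed, "\n")
})

setMethod("show", "CentromereSpec", function(object) {
    cat("CentromereSpec:", object@unitLen, "+", object@spacerLen, "+",
        object@unitLen, "bp element (", elementLength(object), "bp ), AT",
        object@atFraction, "\n")
})

setMethod("show", "ChromosomeBuild", function(object) {
    cat("ChromosomeBuild", lgName(object@lg), ":",
        nrow(object@components), "contig(s),",
        format(object@totalLength, big.mark = ","), "bp\n")
})

#' Call inversions from synteny blocks
#'
#' Within each query chromosome (blocks against its modal target
#' chromosome, sorted by query start), a maximal run of consecutive `-`
#' blocks flanked by `+` blocks is a single inversion. When such a run
#' contains an adjacent pair of `-` blocks whose target intervals ascend
#' (the later block maps higher on the target — the opposite of the
#' descending-target order a single inversion produces), the run is the
#' signature of two serial inversions and is reported as one `double` call
#' with three breakpoint intervals. Each breakpoint interval runs from the
#' end of the last anchor of the preceding block to the start of the first
#' anchor of the following block, in query coordinates.
#'
#' @param blocks data.frame from [chainAnchors()] or [blocksFromPaf()].
#' @return an [InversionCallSet-class].
#' @export
callInversions <- function(blocks) {
    calls <- NULL
    intervals <- NULL
    nextId <- 1L
    for (ch in unique(blocks$q_chrom)) {
        sub <- blocks[blocks$q_chrom == ch, , drop = FALSE]
        tmode <- names(sort(table(sub$t_chrom), decreasing = TRUE))[1]
        sub <- sub[sub$t_chrom == tmode, , drop = FALSE]
        sub <- sub[order(sub$q_start, -sub$q_end), , drop = FALSE]
        ## secondary chains nested inside a larger block (stray anchors
        ## around repeat arrays) carry no junction information; drop them
        if (nrow(sub) > 1L) {
            keep <- rep(TRUE, nrow(sub))
            for (i in seq_len(nrow(sub))) {
                inside <- sub$q_start <= sub$q_start[i] &
                          sub$q_end >= sub$q_end[i]
                inside[i] <- FALSE
                if (any(inside & keep)) keep[i] <- FALSE
            }
            sub <- sub[keep, , drop = FALSE]
        }
        if (nrow(sub) < 2L) {
            warning("chromosome ", ch, " has fewer than 2 blocks; no calls")
            next
        }
        st <- sub$strand
        r <- rle(st)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (ri in seq_along(r$values)) {
            if (r$values[ri] != "-") next
            if (ri == 1L || ri == length(r$values)) next
            if (r$values[ri - 1L] != "+" || r$values[ri + 1L] != "+") next
            run <- sub[starts[ri]:ends[ri], , drop = FALSE]
            prevPlus <- sub[ends[ri - 1L], , drop = FALSE]
            nextPlus <- sub[starts[ri + 1L], , drop = FALSE]
            asc <- integer(0)
            if (nrow(run) > 1L) {
                tmid <- (run$t_start + run$t_end) / 2
                asc <- which(diff(tmid) > 0)
            }
            kind <- if (length(asc) >= 1L) "double" else "single"
            if (length(asc) > 1L)
                warning("inverted run on ", ch, " has ", length(asc),
                        " ascending junctions; reported as one double ",
                        "call at the first junction")
            iv0 <- rbind(
                c(prevPlus$q_end, run$q_start[1L]),
                if (kind == "double")
                    c(run$q_end[asc[1L]], run$q_start[asc[1L] + 1L]),
                c(run$q_end[nrow(run)], nextPlus$q_start))
            ## flanking anchors can abut or marginally overlap the junction;
            ## the breakpoint lies between the two boundary coordinates
            iv0 <- cbind(pmin(iv0[, 1], iv0[, 2]),
                         pmax(iv0[, 2], iv0[, 1]))
            iv0[, 2] <- pmax(iv0[, 2], iv0[, 1] + 1)
            calls <- rbind(calls, data.frame(
                call_id = nextId, chrom = ch, kind = kind,
                stringsAsFactors = FALSE))
            intervals <- rbind(intervals, data.frame(
                call_id = nextId, chrom = ch,
                start = iv0[, 1] + 1, end = iv0[, 2] + 1,
                stringsAsFactors = FALSE))
            nextId <- nextId + 1L
        }
    }
    if (is.null(calls)) {
        calls <- data.frame(call_id = integer(), chrom = character(),
                            kind = character(), stringsAsFactors = FALSE)
        intervals <- data.frame(call_id = integer(), chrom = character(),
                                start = numeric(), end = numeric(),
                                stringsAsFactors = FALSE)
    }
    InversionCallSet(calls, intervals)
}

#' Breakpoint-interval report
#'
#' One row per breakpoint interval with `size_bp = end - start`; the
#' call-level inversion span in Mb (outer span / 1e6, two decimals) is
#' printed on the first row of each call.
#'
#' @param callset an [InversionCallSet-class].
#' @param path optional TSV output path.
#' @return the report data.frame: `lg`, `start`, `end`, `size_bp`,
#'   `span_mb`.
#' @export
reportTable2 <- function(callset, path = NULL) {
    iv <- callset@intervals
    cl <- callset@calls
    out <- data.frame(lg = iv$chrom, start = iv$start, end = iv$end,
                      size_bp = iv$size,
                      span_mb = NA_real_, stringsAsFactors = FALSE)
    for (id in cl$call_id) {
        first <- which(iv$call_id == id)[1]
        out$span_mb[first] <- cl$span_mb[cl$call_id == id]
    }
    if (!is.null(path))
        write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    out
}

#' Build synteny blocks from PAF alignment records
#'
#' Each PAF record spanning at least `minBlockBp` becomes one block;
#' adjacent records on the same chromosome pair and strand with query- and
#' target-side gaps within `maxGap` are merged first (the same gap rule as
#' [chainAnchors()]).
#'
#' @param records data.frame from [readPaf()].
#' @param minBlockBp minimum block span on the query (default 2e4).
#' @param maxGap merge gap bound in bp (default 1e5).
#' @param queryNames,targetNames optional character vectors of known
#'   sequence names; names present in the PAF but not in these sets raise
#'   an error listing them.
#' @return block data.frame as from [chainAnchors()].
#' @export
blocksFromPaf <- function(records, minBlockBp = 2e4, maxGap = 1e5,
                          queryNames = NULL, targetNames = NULL) {
    if (!is.null(queryNames)) {
        missing <- setdiff(unique(records$query_id), queryNames)
        if (length(missing))
            stop("PAF query name(s) not in genome: ",
                 paste(missing, collapse = ", "))
    }
    if (!is.null(targetNames)) {
        missing <- setdiff(unique(records$target_id), targetNames)
        if (length(missing))
            stop("PAF target name(s) not in genome: ",
                 paste(missing, collapse = ", "))
    }
    blocks <- NULL
    grp <- paste(records$query_id, records$target_id, sep = "\r")
    for (g in unique(grp)) {
        sub <- records[grp == g, , drop = FALSE]
        sub <- sub[order(sub$query_start), , drop = FALSE]
        newBlock <- function(i) data.frame(
            q_chrom = sub$query_id[i], q_start = sub$query_start[i],
            q_end = sub$query_end[i], t_chrom = sub$target_id[i],
            t_start = sub$target_start[i], t_end = sub$target_end[i],
            strand = sub$strand[i], n_anchors = 1L,
            span_bp = sub$query_end[i] - sub$query_start[i],
            weight_bp = sub$query_end[i] - sub$query_start[i],
            stringsAsFactors = FALSE)
        cur <- newBlock(1L)
        ## merge only records adjacent on the query: a record of another
        ## strand closes the open block, so merges never leap over an
        ## intervening alignment
        for (i in seq_len(nrow(sub))[-1]) {
            qgap <- sub$query_start[i] - cur$q_end
            tgap <- if (sub$strand[i] == "+")
                sub$target_start[i] - cur$t_end
            else cur$t_start - sub$target_end[i]
            if (sub$strand[i] == cur$strand &&
                qgap >= 0 && qgap <= maxGap && tgap >= 0 && tgap <= maxGap) {
                cur$q_end <- sub$query_end[i]
                cur$t_start <- min(cur$t_start, sub$target_start[i])
                cur$t_end <- max(cur$t_end, sub$target_end[i])
                cur$n_anchors <- cur$n_anchors + 1L
                cur$span_bp <- cur$q_end - cur$q_start
                cur$weight_bp <- cur$weight_bp +
                    (sub$query_end[i] - sub$query_start[i])
            } else {
                blocks <- rbind(blocks, cur)
                cur <- newBlock(i)
            }
        }
        blocks <- rbind(blocks, cur)
    }
    if (is.null(blocks)) {
        return(chainAnchors(data.frame(q_chrom = character(),
                                       q_start = numeric(),
                                       q_end = numeric(),
                                       t_chrom = character(),
                                       t_start = numeric(),
                                       t_end = numeric(),
                                       strand = character(),
                                       length = numeric())))
    }
    blocks <- blocks[blocks$span_bp >= minBlockBp, , drop = FALSE]
    blocks <- blocks[order(blocks$q_chrom, blocks$q_start), , drop = FALSE]
    rownames(blocks) <- NULL
    blocks
}

#' Annotate breakpoint intervals with contig-boundary context
#'
#' Given the AGP of the query build, flags each breakpoint interval as
#' `within contig` (the interval lies inside a single contig component) or
#' `between contigs` (it touches a gap or spans components).
#'
#' @param callset an [InversionCallSet-class].
#' @param agp AGP component data.frame of the query assembly.
#' @return the intervals data.frame with an added `contig_context` column.
#' @export
annotateContigContext <- function(callset, agp) {
    iv <- callset@intervals
    iv$contig_context <- vapply(seq_len(nrow(iv)), function(i) {
        sub <- agp[agp$object_id == iv$chrom[i] &
                   agp$component_type == "contig", , drop = FALSE]
        inside <- sub$object_start <= iv$start[i] &
                  sub$object_end >= iv$end[i] - 1
        if (any(inside)) "within contig" else "between contigs"
    }, "")
    iv
}
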