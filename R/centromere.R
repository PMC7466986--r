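## centromere_scan: tandem-array detection (simplified seed-and-extend
## detector plus a Tandem Repeats Finder .dat import), the AT/length/
## coverage candidate filter, family clustering at 95% identity, and
## genome-wide occurrence counting with density tracks.

#' Detect tandem-repeat arrays by k-mer lag recurrence
#'
#' A position seeds a candidate period `p` when its `seedK`-mer recurs at
#' lag `p` within `[minPeriod, maxPeriod]`. Seeded loci are extended copy
#' by copy in both directions while consecutive copies agree at
#' `minCopyIdentity` (ungapped), the consensus is the per-column majority
#' over full copies, and overlapping calls are resolved by keeping the
#' higher `copy_number * period` product. This is a deliberately simple
#' substitution-model detector; indel-rich real data should go through
#' [parseTrfDat()] instead.
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector).
#' @param minPeriod,maxPeriod period search range in bp (defaults 50, 600).
#' @param minCopies minimum copies per reported array (default 2).
#' @param seedK seed k-mer length (default 15).
#' @param minCopyIdentity ungapped identity required between consecutive
#'   copies during extension (default 0.8).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `period`, `copy_number`, `consensus`, `at_fraction`, `mean_identity`.
#' @export
detectTandemArrays <- function(genome, minPeriod = 50L, maxPeriod = 600L,
                               minCopies = 2L, seedK = 15L,
                               minCopyIdentity = 0.8) {
    stopifnot(minPeriod <= maxPeriod, minCopies >= 2L)
    if (!is.character(genome)) genome <- as.character(genome)
    cand <- NULL
    for (ch in names(genome)) {
        s <- genome[[ch]]
        len <- nchar(s)
        if (len < 2L * minPeriod) next
        seeds <- tandem_seeds_cpp(s, as.integer(seedK),
                                  as.integer(minPeriod),
                                  as.integer(maxPeriod))
        if (nrow(seeds) == 0L) next
        for (p in sort(unique(seeds[, "lag"]))) {
            pos <- sort(seeds[seeds[, "lag"] == p, "pos"])
            groups <- split(pos, cumsum(c(TRUE, diff(pos) > p)))
            for (gp in groups) {
                arr <- extendTandem(s, len, min(gp), p, minCopyIdentity)
                if (is.null(arr) || arr$n < minCopies) next
                ## a lag that is a multiple of the physical period reads the
                ## array at m units per copy; reduce to the primitive period
                ## (probe a mid-array copy: the edges may carry background
                ## absorbed by boundary refinement)
                midOff <- (arr$n %/% 2L) * p
                midCopy <- substr(s, arr$start + midOff + 1L,
                                  arr$start + midOff + p)
                pp <- fundamentalPeriod(midCopy, minPeriod, minCopyIdentity)
                if (pp < p) {
                    arr2 <- extendTandem(s, len, min(gp), pp, minCopyIdentity)
                    if (!is.null(arr2) && arr2$n >= minCopies) arr <- arr2
                    else pp <- p
                } else pp <- p
                copies <- substring(s, seq(arr$start, by = pp,
                                           length.out = arr$n) + 1L,
                                    seq(arr$start + pp, by = pp,
                                        length.out = arr$n))
                cons <- majorityConsensus(copies)
                ident <- vapply(copies, hammingIdentity, 1.0, b = cons,
                                USE.NAMES = FALSE)
                cand <- rbind(cand, data.frame(
                    chrom = ch, start = arr$start, end = arr$end,
                    period = pp,
                    copy_number = (arr$end - arr$start) / pp,
                    consensus = cons, at_fraction = atFractionOf(cons),
                    mean_identity = mean(ident), stringsAsFactors = FALSE))
            }
        }
    }
    if (is.null(cand))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), period = integer(),
                          copy_number = numeric(), consensus = character(),
                          at_fraction = numeric(), mean_identity = numeric(),
                          stringsAsFactors = FALSE))
    resolveOverlaps(cand)
}

## primitive period of a repeat unit: the smallest divisor q of its length
## at which the unit matches itself shifted by q (ungapped), or the full
## length when none qualifies
fundamentalPeriod <- function(unit, minPeriod, minCopyIdentity) {
    p <- nchar(unit)
    mmax <- p %/% minPeriod
    if (mmax < 2L) return(p)
    for (m in seq.int(mmax, 2L)) {
        if (p %% m != 0L) next
        q <- p %/% m
        id <- hammingIdentity(substr(unit, 1L, p - q),
                              substr(unit, q + 1L, p))
        if (!is.na(id) && id >= minCopyIdentity) return(q)
    }
    p
}

## extend a tandem locus copy-by-copy in both directions
extendTandem <- function(s, len, s0, p, minCopyIdentity) {
    if (s0 + 2L * p > len) return(NULL)
    copyAt <- function(a) substr(s, a + 1L, a + p)
    start <- s0
    cur <- copyAt(start)
    n <- 1L
    while (start + (n + 1L) * p <= len) {
        nxt <- copyAt(start + n * p)
        if (hammingIdentity(cur, nxt) < minCopyIdentity) break
        cur <- nxt
        n <- n + 1L
    }
    cur <- copyAt(start)
    while (start - p >= 0L) {
        prv <- copyAt(start - p)
        if (hammingIdentity(prv, cur) < minCopyIdentity) break
        start <- start - p
        cur <- prv
        n <- n + 1L
    }
    if (n < 2L) return(NULL)
    end <- start + n * p
    ## sub-period boundary refinement: the seed may sit out of phase with
    ## the physical array, leaving partial copies at either edge; walk
    ## outward base by base at lag p while the running identity holds
    chars <- function(a, b) if (b < a) character(0) else
        strsplit(substr(s, a, b), "")[[1]]
    dmaxL <- min(p - 1L, start)
    if (dmaxL > 0L) {
        outer <- rev(chars(start - dmaxL + 1L, start))
        inner <- rev(chars(start + p - dmaxL + 1L, start + p))
        run <- cumsum(outer == inner) / seq_len(dmaxL)
        ok <- which(run >= minCopyIdentity)
        if (length(ok)) start <- start - max(ok)
    }
    dmaxR <- min(p - 1L, len - end)
    if (dmaxR > 0L) {
        outer <- chars(end + 1L, end + dmaxR)
        inner <- chars(end - p + 1L, end - p + dmaxR)
        run <- cumsum(outer == inner) / seq_len(dmaxR)
        ok <- which(run >= minCopyIdentity)
        if (length(ok)) end <- end + max(ok)
    }
    list(start = start, end = end, n = n)
}

## per-column majority over equal-length copies; ties broken alphabetically
majorityConsensus <- function(copies) {
    m <- do.call(rbind, strsplit(copies, ""))
    paste(apply(m, 2L, function(col) {
        tab <- sort(table(col), decreasing = TRUE)
        names(tab)[1]
    }), collapse = "")
}

## keep the higher copy_number * period call among overlapping arrays
resolveOverlaps <- function(cand) {
    ## equal-score ties (an array read at twice its fundamental period has
    ## the same copy_number * period product) resolve to the smaller period
    score <- cand$copy_number * cand$period
    o <- order(-score, cand$period, cand$chrom, cand$start)
    cand <- cand[o, , drop = FALSE]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        prior <- which(keep & cand$chrom == cand$chrom[i])
        clash <- any(cand$start[prior] < cand$end[i] &
                     cand$end[prior] > cand$start[i])
        keep[i] <- !clash
    }
    out <- cand[keep, , drop = FALSE]
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Import Tandem Repeats Finder .dat output
#'
#' Parses the `Sequence:` headers and space-separated data rows of TRF
#' (v4.09) `.dat` files into the internal tandem-array layout. TRF's
#' 1-based inclusive coordinates become 0-based half-open. Malformed data
#' rows are skipped with a warning.
#'
#' @param path path to a `.dat` file.
#' @return data.frame in the [detectTandemArrays()] layout.
#' @export
parseTrfDat <- function(path) {
    lines <- readLines(path)
    chrom <- NA_character_
    rows <- list()
    nBad <- 0L
    for (ln in lines) {
        if (grepl("^Sequence:", ln)) {
            chrom <- trimws(sub("^Sequence:", "", ln))
            chrom <- sub("\\s.*$", "", chrom)
            next
        }
        if (!grepl("^[0-9]", ln)) next
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(f) < 15L || is.na(suppressWarnings(as.numeric(f[1])))) {
            nBad <- nBad + 1L
            next
        }
        start1 <- as.numeric(f[1]); end1 <- as.numeric(f[2])
        period <- as.integer(f[3]); copies <- as.numeric(f[4])
        pm <- as.numeric(f[6]); cons <- f[14]
        if (any(is.na(c(start1, end1, period, copies, pm))) ||
            !grepl("^[ACGTN]+$", cons)) {
            nBad <- nBad + 1L
            next
        }
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = start1 - 1, end = end1,
            period = period, copy_number = copies, consensus = cons,
            at_fraction = atFractionOf(cons), mean_identity = pm / 100,
            stringsAsFactors = FALSE)
    }
    if (nBad > 0L)
        warning(nBad, " malformed TRF data row(s) skipped")
    if (length(rows) == 0L)
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), period = integer(),
                          copy_number = numeric(), consensus = character(),
                          at_fraction = numeric(), mean_identity = numeric(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Centromere-candidate filter on tandem arrays
#'
#' Keeps arrays whose consensus is strictly more than `atMin` AT and whose
#' period is strictly longer than `unitMinLen` bp (the boundary cases 60.0%
#' AT and 80 bp are rejected). The present-on-all-chromosomes condition is
#' a family-level test applied after clustering (see
#' [centromereCandidates()]).
#'
#' @param arrays data.frame from [detectTandemArrays()] / [parseTrfDat()].
#' @param atMin minimum AT fraction, exclusive (default 0.60).
#' @param unitMinLen minimum period in bp, exclusive (default 80).
#' @return the filtered data.frame.
#' @export
filterCandidates <- function(arrays, atMin = 0.60, unitMinLen = 80L) {
    out <- arrays[arrays$at_fraction > atMin & arrays$period > unitMinLen, ,
                  drop = FALSE]
    rownames(out) <- NULL
    out
}

## cyclic-rotation- and strand-maximized identity between two consensi;
## unequal lengths fall back to global alignment identity
consensusIdentity <- function(a, b) {
    strands <- c(b, revcompChar(b))
    if (nchar(a) == nchar(b)) {
        n <- nchar(a)
        a2 <- strrep(a, 2L)
        rots <- substring(a2, seq_len(n), seq_len(n) + n - 1L)
        max(vapply(strands, function(bs)
            max(vapply(rots, hammingIdentity, 1.0, b = bs,
                       USE.NAMES = FALSE)), 1.0, USE.NAMES = FALSE))
    } else {
        max(vapply(strands, function(bs) {
            aln <- Biostrings::pairwiseAlignment(a, bs, type = "global")
            alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
            Biostrings::nmatch(aln) / alnLen
        }, 1.0, USE.NAMES = FALSE))
    }
}

#' Cluster tandem arrays into repeat families
#'
#' Greedy centroid clustering: arrays sorted by `copy_number * period`
#' descending join the first family whose consensus matches at
#' `identityThreshold` or better, where identity is maximized over cyclic
#' rotations (tandem phase is arbitrary) and both strands; otherwise the
#' array founds a new family whose consensus it donates.
#'
#' @param arrays data.frame from [detectTandemArrays()] / [parseTrfDat()].
#' @param identityThreshold clustering identity (default 0.95).
#' @return list: `families` (data.frame `family_id`, `consensus`,
#'   `n_members`, `n_chroms`, `chroms`) and `members` (the input arrays
#'   with a `family_id` column).
#' @export
clusterFamilies <- function(arrays, identityThreshold = 0.95) {
    if (nrow(arrays) == 0L)
        return(list(families = data.frame(family_id = integer(),
                                          consensus = character(),
                                          n_members = integer(),
                                          n_chroms = integer(),
                                          chroms = character(),
                                          stringsAsFactors = FALSE),
                    members = cbind(arrays, family_id = integer(0))))
    score <- arrays$copy_number * arrays$period
    o <- order(-score, arrays$chrom, arrays$start)
    arrays <- arrays[o, , drop = FALSE]
    famCons <- character()
    famId <- integer(nrow(arrays))
    for (i in seq_len(nrow(arrays))) {
        assigned <- 0L
        for (f in seq_along(famCons)) {
            if (consensusIdentity(famCons[f], arrays$consensus[i]) >=
                identityThreshold) {
                assigned <- f
                break
            }
        }
        if (assigned == 0L) {
            famCons <- c(famCons, arrays$consensus[i])
            assigned <- length(famCons)
        }
        famId[i] <- assigned
    }
    arrays$family_id <- famId
    families <- do.call(rbind, lapply(seq_along(famCons), function(f) {
        sub <- arrays[arrays$family_id == f, , drop = FALSE]
        data.frame(family_id = f, consensus = famCons[f],
                   n_members = nrow(sub),
                   n_chroms = length(unique(sub$chrom)),
                   chroms = paste(sort(unique(sub$chrom)), collapse = ","),
                   stringsAsFactors = FALSE)
    }))
    arrays <- arrays[order(arrays$chrom, arrays$start), , drop = FALSE]
    rownames(arrays) <- NULL
    list(families = families, members = arrays)
}

#' Centromere-candidate families
#'
#' Applies the candidate filter (AT strictly > `atMin`, period strictly >
#' `unitMinLen`), clusters the survivors into families and keeps the
#' families present on all `nChroms` chromosomes (at least one member
#' array per chromosome).
#'
#' @inheritParams filterCandidates
#' @inheritParams clusterFamilies
#' @param nChroms number of chromosomes the genome has.
#' @param requireAllChroms apply the coverage test (default TRUE).
#' @return as [clusterFamilies()], with `families` restricted to the
#'   candidates.
#' @export
centromereCandidates <- function(arrays, nChroms, atMin = 0.60,
                                 unitMinLen = 80L,
                                 identityThreshold = 0.95,
                                 requireAllChroms = TRUE) {
    kept <- filterCandidates(arrays, atMin, unitMinLen)
    cl <- clusterFamilies(kept, identityThreshold)
    fams <- cl$families
    if (requireAllChroms)
        fams <- fams[fams$n_chroms == nChroms, , drop = FALSE]
    rownames(fams) <- NULL
    list(families = fams,
         members = cl$members[cl$members$family_id %in% fams$family_id, ,
                              drop = FALSE])
}

#' Count genome-wide occurrences of a consensus sequence
#'
#' Seeded ungapped semi-global scan of the consensus over both strands of
#' every chromosome; candidate placements share a `seedK`-mer with the
#' consensus on a matching diagonal and are scored by ungapped identity.
#' Overlapping candidates are resolved best-first (higher identity, then
#' leftmost). The seed length is pigeonhole-complete for the default
#' identity threshold and consensus lengths of ~88 bp and above, so the
#' scan finds every placement an exhaustive all-offsets scorer would.
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector).
#' @param consensus consensus sequence (character).
#' @param minIdentity minimum ungapped identity (default 0.95).
#' @param seedK seed k-mer length (default 13).
#' @return list: `count` and `positions` (data.frame `chrom`, `start`,
#'   `end` 0-based half-open, `strand`, `identity`).
#' @export
countOccurrences <- function(genome, consensus, minIdentity = 0.95,
                             seedK = 13L) {
    stopifnot(nchar(consensus) > 0L)
    if (!is.character(genome)) genome <- as.character(genome)
    L <- nchar(consensus)
    rcCons <- revcompChar(consensus)
    pos <- NULL
    for (ch in names(genome)) {
        hits <- NULL
        for (strand in c("+", "-")) {
            m <- scan_consensus_cpp(genome[[ch]],
                                    if (strand == "+") consensus else rcCons,
                                    as.integer(seedK), minIdentity)
            if (nrow(m))
                hits <- rbind(hits, data.frame(
                    start = m[, "start"], identity = m[, "identity"],
                    strand = strand, stringsAsFactors = FALSE))
        }
        if (is.null(hits)) next
        hits <- hits[order(-hits$identity, hits$start, hits$strand), ,
                     drop = FALSE]
        taken <- NULL
        for (i in seq_len(nrow(hits))) {
            s <- hits$start[i]
            if (!is.null(taken) && any(taken$start < s + L &
                                       taken$end > s)) next
            taken <- rbind(taken, data.frame(
                start = s, end = s + L, strand = hits$strand[i],
                identity = hits$identity[i], stringsAsFactors = FALSE))
        }
        pos <- rbind(pos, cbind(chrom = ch, taken))
    }
    if (is.null(pos)) {
        pos <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          identity = numeric(), stringsAsFactors = FALSE)
    } else {
        pos <- pos[order(pos$chrom, pos$start), , drop = FALSE]
        rownames(pos) <- NULL
    }
    list(count = nrow(pos), positions = pos)
}

#' Detect a unit--spacer--unit sub-structure in a repeat consensus
#'
#' Self-comparison of the consensus: when its two ends are (near-)identical
#' direct repeats — as in a satellite element built from two identical
#' sub-units flanking a spacer — the largest terminal repeat with ungapped
#' identity at least `minIdentity` is reported, so the sub-unit monomer can
#' be used instead of the full element.
#'
#' @param consensus consensus sequence (character).
#' @param minUnit smallest sub-unit length considered, bp (default 20).
#' @param minIdentity ungapped identity between the two terminal repeats
#'   (default 0.9).
#' @return list with `unit_len`, `spacer_len`, `identity`, `unit` (the
#'   5' copy), or `NULL` when no such structure is detected.
#' @export
detectSubunit <- function(consensus, minUnit = 20L, minIdentity = 0.9) {
    L <- nchar(consensus)
    if (L < 2L * minUnit) return(NULL)
    best <- NULL
    for (u in seq.int(minUnit, L %/% 2L)) {
        id <- hammingIdentity(substr(consensus, 1L, u),
                              substr(consensus, L - u + 1L, L))
        if (id >= minIdentity) best <- list(u = u, id = id)
    }
    if (is.null(best)) return(NULL)
    list(unit_len = best$u, spacer_len = L - 2L * best$u,
         identity = best$id, unit = substr(consensus, 1L, best$u))
}

#' Binned occurrence density per chromosome
#'
#' @param positions data.frame with `chrom` and `start` (0-based), e.g.
#'   from [countOccurrences()].
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param binSize bin width in bp (default 1e5).
#' @return data.frame: `chrom`, `bin_start`, `bin_end`, `count`; all-zero
#'   rows are emitted for chromosomes without occurrences.
#' @export
densityTrack <- function(positions, chromLengths, binSize = 1e5) {
    stopifnot(binSize >= 1)
    out <- NULL
    for (ch in names(chromLengths)) {
        len <- chromLengths[[ch]]
        p <- positions$start[positions$chrom == ch]
        if (any(p >= len | p < 0))
            stop("position beyond chromosome length on ", ch)
        nb <- ceiling(len / binSize)
        counts <- tabulate(floor(p / binSize) + 1L, nbins = nb)
        out <- rbind(out, data.frame(
            chrom = ch, bin_start = (seq_len(nb) - 1) * binSize,
            bin_end = pmin(seq_len(nb) * binSize, len), count = counts,
            stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
}
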