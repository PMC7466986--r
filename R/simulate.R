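## synthetic_data: paired genomes with planted inversions, centromeric
## satellite arrays, fragmented/chimeric contigs and a sex-specific marker
## map, all with recorded ground truth.

#' Construct a CentromereSpec
#'
#' The planted centromeric element is a unit--spacer--unit structure: two
#' identical direct repeats of `unitLen` bp flanking a `spacerLen` bp spacer
#' (88 + 82 + 88 = 258 bp by default). The element is built with an exact
#' AT-base count so the realized AT fraction equals `atFraction` up to
#' rounding, guaranteeing it clears the strictly-greater-than-60%-AT
#' centromere-candidate filter at the default 0.70.
#'
#' @param unitLen sub-unit length in bp (default 88).
#' @param spacerLen spacer length in bp (default 82).
#' @param atFraction AT fraction of the constructed element (default 0.70).
#' @param copiesPerArray tandem copies planted per array (default 20).
#' @param positionFraction array midpoint as fraction of chromosome length,
#'   recycled over chromosomes; 0.5 = metacentric (default 0.5).
#' @param mutationRate per-copy substitution rate (default 0.02), so that
#'   clustering at 95% identity is exercised.
#' @return a [CentromereSpec-class] object.
#' @export
#' @examples
#' elementLength(CentromereSpec()) # 258
CentromereSpec <- function(unitLen = 88L, spacerLen = 82L, atFraction = 0.70,
                           copiesPerArray = 20L, positionFraction = 0.5,
                           mutationRate = 0.02) {
    new("CentromereSpec", unitLen = as.integer(unitLen),
        spacerLen = as.integer(spacerLen), atFraction = atFraction,
        copiesPerArray = as.integer(copiesPerArray),
        positionFraction = positionFraction, mutationRate = mutationRate)
}

#' Length of the unit--spacer--unit element
#'
#' @param spec a [CentromereSpec-class].
#' @return integer element length, `2 * unitLen + spacerLen`.
#' @export
elementLength <- function(spec) {
    2L * spec@unitLen + spec@spacerLen
}

#' Build the centromeric element sequence of a CentromereSpec
#'
#' Draws the two component sequences (unit, spacer) with exact AT counts and
#' concatenates unit + spacer + unit. Uses the current RNG state.
#'
#' @param spec a [CentromereSpec-class].
#' @return a single character string of length [elementLength()].
#' @export
centromereElement <- function(spec) {
    unit <- randomSeqExactAT(spec@unitLen, spec@atFraction)
    spacer <- randomSeqExactAT(spec@spacerLen, spec@atFraction)
    paste0(unit, spacer, unit)
}

#' Construct planted-inversion specifications
#'
#' One row per rearrangement. A `single` inversion reverse-complements
#' `[start, end)`. A `double` is two serial inversions applied in order:
#' `[start, end)` then `[second_start, second_end)`; the intervals must be
#' ordered and may share a boundary (the default generator plants them
#' adjacent, which yields the three-breakpoint signature of the serial
#' double inversion).
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open bounds of the (first) inverted interval.
#' @param kind `"single"` or `"double"`.
#' @param second_start,second_end second interval for doubles, `NA` otherwise.
#' @return validated data.frame of inversion specs.
#' @export
inversionSpecs <- function(chrom, start, end, kind = "single",
                           second_start = NA_real_, second_end = NA_real_) {
    out <- data.frame(chrom = chrom, start = start, end = end, kind = kind,
                      second_start = second_start, second_end = second_end,
                      stringsAsFactors = FALSE)
    stopifnot(all(out$kind %in% c("single", "double")),
              all(out$start < out$end))
    dbl <- out$kind == "double"
    if (any(dbl)) {
        stopifnot(!any(is.na(out$second_start[dbl])),
                  all(out$second_start[dbl] < out$second_end[dbl]),
                  all(out$second_start[dbl] >= out$start[dbl]))
    }
    out
}

emptyInversionSpecs <- function() {
    inversionSpecs(character(), numeric(), numeric(), character(),
                   numeric(), numeric())
}

#' Construct a SimConfig
#'
#' Defaults describe the desk-scale study system: 23 chromosomes of 2 Mb at
#' GC 0.46, 100 markers/Mb, 250 kb mean contigs, female:male map expansion
#' 1.3 with 55 cM of male map per chromosome, 0.2% substitution divergence
#' between the genome pair, and one centromeric satellite array per
#' chromosome (metacentric by default) plus AT-rich decoy arrays on three
#' chromosomes.
#'
#' @param nChromosomes haploid chromosome number (default 23).
#' @param chromLength chromosome length(s) in bp, scalar or per-chromosome
#'   (default 2e6).
#' @param gcFraction GC fraction (default 0.46).
#' @param inversionSpecs data.frame from [inversionSpecs()] (default: none).
#' @param centromere a [CentromereSpec-class] (default [CentromereSpec()]).
#' @param markerDensity markers per Mb (default 100).
#' @param contigMeanLen mean contig length in bp (default 250000).
#' @param chimeraRate chimeric-contig probability (default 0).
#' @param femaleMaleExpansion female:male map ratio (default 1.3).
#' @param maleChromMap male map length per chromosome in cM (default 55).
#' @param suppressWindow width of the zero-recombination pericentromeric
#'   window in bp (default: 20% of the shortest chromosome, i.e. 4e5 at
#'   the default scale).
#' @param snpDivergence per-base substitution divergence of the query genome
#'   (default 0.002).
#' @param flankK marker flank length per side in bp (default 50).
#' @param nDecoyChroms chromosomes carrying a decoy AT-rich array (default 3).
#' @param repeatBackground add a dispersed repeat background (default FALSE).
#' @param inversionMapGaps collapse marker cM inside planted inversions
#'   (default FALSE).
#' @param seed master seed (default 1).
#' @return a [SimConfig-class] object.
#' @export
SimConfig <- function(nChromosomes = 23L, chromLength = 2e6,
                      gcFraction = 0.46,
                      inversionSpecs = emptyInversionSpecs(),
                      centromere = CentromereSpec(),
                      markerDensity = 100, contigMeanLen = 250000,
                      chimeraRate = 0, femaleMaleExpansion = 1.3,
                      maleChromMap = 55,
                      suppressWindow = 0.2 * min(chromLength),
                      snpDivergence = 0.002, flankK = 50L,
                      nDecoyChroms = 3L, repeatBackground = FALSE,
                      inversionMapGaps = FALSE, seed = 1L) {
    nChromosomes <- as.integer(nChromosomes)
    lens <- rep_len(chromLength, nChromosomes)
    names(lens) <- lgName(seq_len(nChromosomes))
    new("SimConfig", nChromosomes = nChromosomes, chromLengths = lens,
        gcFraction = gcFraction, inversionSpecs = inversionSpecs,
        centromere = centromere, markerDensity = markerDensity,
        contigMeanLen = contigMeanLen, chimeraRate = chimeraRate,
        femaleMaleExpansion = femaleMaleExpansion,
        maleChromMap = maleChromMap, suppressWindow = suppressWindow,
        snpDivergence = snpDivergence, flankK = as.integer(flankK),
        nDecoyChroms = as.integer(min(nDecoyChroms, nChromosomes)),
        repeatBackground = repeatBackground,
        inversionMapGaps = inversionMapGaps, seed = as.integer(seed))
}

#' Default planted rearrangements for a SimConfig
#'
#' Plants one serial double inversion (three breakpoints, on the first
#' chromosome) and three single inversions, mirroring the supergene
#' configuration studied on the real genome: intervals are placed at fixed
#' fractions of chromosome length, away from sequence ends.
#'
#' @param config a [SimConfig-class].
#' @return an [inversionSpecs()] data.frame.
#' @export
defaultInversionSpecs <- function(config) {
    lens <- config@chromLengths
    stopifnot(config@nChromosomes >= 4L)
    nm <- names(lens)
    rbind(
        inversionSpecs(nm[1], round(0.35 * lens[1]), round(0.55 * lens[1]),
                       kind = "double",
                       second_start = round(0.55 * lens[1]),
                       second_end = round(0.75 * lens[1])),
        inversionSpecs(nm[2], round(0.55 * lens[2]), round(0.85 * lens[2])),
        inversionSpecs(nm[3], round(0.10 * lens[3]), round(0.40 * lens[3])),
        inversionSpecs(nm[4], round(0.58 * lens[4]), round(0.92 * lens[4]))
    )
}

## expand spec rows into the ordered list of intervals actually applied
expandInversionIntervals <- function(specs) {
    if (nrow(specs) == 0L)
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE))
    out <- lapply(seq_len(nrow(specs)), function(i) {
        r <- specs[i, ]
        if (r$kind == "double") {
            data.frame(chrom = r$chrom, start = c(r$start, r$second_start),
                       end = c(r$end, r$second_end), stringsAsFactors = FALSE)
        } else {
            data.frame(chrom = r$chrom, start = r$start, end = r$end,
                       stringsAsFactors = FALSE)
        }
    })
    do.call(rbind, out)
}

#' Simulate the reference genome with planted centromeric arrays
#'
#' Draws i.i.d. bases at the configured GC fraction, builds one genome-wide
#' centromeric element (see [centromereElement()]) and plants one tandem
#' array of `copiesPerArray` independently mutated copies per chromosome at
#' its `positionFraction`; decoy AT-rich arrays go on the first
#' `nDecoyChroms` chromosomes. Fully reproducible under `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `truth`
#'   (a [SimTruth-class] with centromere intervals populated).
#' @export
simulateReference <- function(config) {
    set.seed(config@seed)
    spec <- config@centromere
    element <- centromereElement(spec)
    decoyElement <- randomSeqExactAT(120L, 0.75)
    posFrac <- rep_len(spec@positionFraction, config@nChromosomes)
    lens <- config@chromLengths
    arrLen <- nchar(element) * spec@copiesPerArray
    if (any(arrLen > lens))
        stop("centromeric array (", arrLen, " bp) longer than chromosome")

    seqs <- character(config@nChromosomes)
    cen <- vector("list", config@nChromosomes)
    for (i in seq_len(config@nChromosomes)) {
        len <- as.integer(lens[i])
        s <- random_dna_cpp(len, config@gcFraction)
        copies <- vapply(seq_len(spec@copiesPerArray), function(j)
            mutate_dna_cpp(element, spec@mutationRate), "")
        arr <- paste(copies, collapse = "")
        start <- round(posFrac[i] * len - arrLen / 2)
        start <- max(0, min(start, len - arrLen))
        substr(s, start + 1, start + arrLen) <- arr
        rows <- data.frame(chrom = names(lens)[i], start = start,
                           end = start + arrLen, family = "centromere",
                           consensus = element, stringsAsFactors = FALSE)
        if (i <= config@nDecoyChroms) {
            dLen <- nchar(decoyElement) * 10L
            dStart <- round(0.15 * len)
            dCopies <- vapply(seq_len(10L), function(j)
                mutate_dna_cpp(decoyElement, spec@mutationRate), "")
            substr(s, dStart + 1, dStart + dLen) <- paste(dCopies, collapse = "")
            rows <- rbind(rows, data.frame(
                chrom = names(lens)[i], start = dStart, end = dStart + dLen,
                family = "decoy", consensus = decoyElement,
                stringsAsFactors = FALSE))
        }
        if (config@repeatBackground) {
            bg <- random_dna_cpp(500L, config@gcFraction)
            at <- sort(sample.int(len - 500L, 20L))
            for (p in at) substr(s, p + 1, p + 500L) <- bg
        }
        seqs[i] <- s
        cen[[i]] <- rows
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(lens)
    truth <- new("SimTruth", chromLengths = lens,
                 inversions = emptyInversionSpecs(),
                 centromeres = do.call(rbind, cen),
                 contigs = data.frame(), markers = data.frame())
    list(genome = genome, truth = truth)
}

#' Apply planted inversions to a genome
#'
#' Each specified interval is replaced by its reverse complement; the two
#' intervals of a `double` are applied sequentially in listed order. Rows
#' whose outer spans overlap on one chromosome are rejected (apply them
#' sequentially through repeated calls instead).
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param specs an [inversionSpecs()] data.frame.
#' @return the rearranged genome.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrA = "ACGTACGT"))
#' sp <- inversionSpecs("chrA", 1, 5)
#' as.character(applyInversions(g, sp)) # "ATACGCGT"
applyInversions <- function(genome, specs) {
    if (nrow(specs) == 0L) return(genome)
    stopifnot(all(specs$chrom %in% names(genome)))
    outer_end <- ifelse(specs$kind == "double", specs$second_end, specs$end)
    for (ch in unique(specs$chrom)) {
        sub <- specs[specs$chrom == ch, , drop = FALSE]
        oe <- outer_end[specs$chrom == ch]
        if (nrow(sub) > 1L) {
            o <- order(sub$start)
            if (any(sub$start[o][-1] < oe[o][-nrow(sub)]))
                stop("overlapping inversion specs on ", ch,
                     " applied simultaneously; apply them sequentially")
        }
        if (any(oe > Biostrings::width(genome)[names(genome) == ch]))
            stop("inversion interval out of bounds on ", ch)
    }
    iv <- expandInversionIntervals(specs)
    for (i in seq_len(nrow(iv))) {
        ch <- iv$chrom[i]
        x <- genome[[ch]]
        rng <- IRanges::IRanges(iv$start[i] + 1L, iv$end[i])
        seg <- Biostrings::extractAt(x, rng)[[1L]]
        genome[[ch]] <- Biostrings::replaceAt(
            x, rng, Biostrings::reverseComplement(seg))
    }
    genome
}

#' Map positions through a set of planted inversions
#'
#' Applies the coordinate transform of each inverted interval in order: a
#' 0-based position `p` inside `[s, e)` becomes `s + e - 1 - p`. Used to
#' carry marker and array truth from reference to query coordinates.
#'
#' @param pos 0-based positions on `chrom`.
#' @param chrom chromosome name (scalar).
#' @param specs an [inversionSpecs()] data.frame.
#' @return mapped 0-based positions.
#' @export
mapThroughInversions <- function(pos, chrom, specs) {
    iv <- expandInversionIntervals(specs)
    iv <- iv[iv$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
        inside <- pos >= iv$start[i] & pos < iv$end[i]
        pos[inside] <- iv$start[i] + iv$end[i] - 1 - pos[inside]
    }
    pos
}

#' Fragment a genome into contigs with optional chimeric joins
#'
#' Chromosomes are cut at exponentially spaced points (mean `meanLen`).
#' With probability `chimeraRate` a fragment is joined to a random fragment
#' from a different chromosome, forming a chimeric contig with no junction
#' sequence signature. Each emitted contig is reverse-complemented with
#' probability 0.5. Source intervals (and chimera flags) are recorded in
#' the returned truth.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param truth a [SimTruth-class] to update.
#' @param meanLen mean fragment length in bp.
#' @param chimeraRate probability of a chimeric join per fragment.
#' @param seed optional seed; if `NULL` the current RNG state is used.
#' @return list with `contigs` (DNAStringSet) and `truth` (updated).
#' @export
fragmentIntoContigs <- function(genome, truth, meanLen, chimeraRate = 0,
                                seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    frags <- list()
    for (ch in names(genome)) {
        len <- Biostrings::width(genome[names(genome) == ch])
        cuts <- numeric()
        p <- 0
        repeat {
            p <- p + stats::rexp(1L, rate = 1 / meanLen)
            if (p >= len) break
            cuts <- c(cuts, floor(p))
        }
        bounds <- unique(c(0, cuts, len))
        for (j in seq_len(length(bounds) - 1L)) {
            frags[[length(frags) + 1L]] <- data.frame(
                chrom = ch, start = bounds[j], end = bounds[j + 1L],
                stringsAsFactors = FALSE)
        }
    }
    frag <- do.call(rbind, frags)
    n <- nrow(frag)
    used <- rep(FALSE, n)
    seeker <- runif(n) < chimeraRate
    contigs <- list()
    parts <- list()
    for (i in seq_len(n)) {
        if (used[i]) next
        used[i] <- TRUE
        partRows <- frag[i, , drop = FALSE]
        if (seeker[i]) {
            cand <- which(!used & frag$chrom != frag$chrom[i])
            if (length(cand)) {
                j <- if (length(cand) == 1L) cand else sample(cand, 1L)
                used[j] <- TRUE
                partRows <- rbind(partRows, frag[j, , drop = FALSE])
            }
        }
        partRows$strand <- "+"
        segs <- vapply(seq_len(nrow(partRows)), function(r)
            as.character(Biostrings::subseq(
                genome[[partRows$chrom[r]]],
                partRows$start[r] + 1L, partRows$end[r])), "")
        cseq <- paste(segs, collapse = "")
        if (runif(1L) < 0.5) {
            cseq <- revcompChar(cseq)
            partRows <- partRows[rev(seq_len(nrow(partRows))), , drop = FALSE]
            partRows$strand <- "-"
        }
        widths <- partRows$end - partRows$start
        partRows$contig_start <- cumsum(c(0, widths[-length(widths)]))
        partRows$contig_end <- cumsum(widths)
        partRows$chimeric <- nrow(partRows) > 1L
        contigs[[length(contigs) + 1L]] <- cseq
        parts[[length(parts) + 1L]] <- partRows
    }
    ids <- sprintf("tig%05d", seq_along(contigs))
    ctg <- Biostrings::DNAStringSet(unlist(contigs))
    names(ctg) <- ids
    for (i in seq_along(parts)) {
        parts[[i]]$contig_id <- ids[i]
        parts[[i]]$part <- seq_len(nrow(parts[[i]]))
    }
    truth@contigs <- do.call(rbind, parts)
    rownames(truth@contigs) <- NULL
    list(contigs = ctg, truth = truth)
}

## integrated genetic position (cM) at 0-based bp positions, given a
## zero-rate window [w0, w1) and a uniform rate elsewhere totalling totalCm
integratedCm <- function(pos, len, w0, w1, totalCm) {
    w0 <- max(0, w0); w1 <- min(len, w1)
    active <- len - (w1 - w0)
    if (active <= 0)
        stop("recombination-suppression window covers the whole chromosome; ",
             "reduce suppressWindow relative to chromosome length")
    rate <- totalCm / active
    below <- pmin(pos, w0) + pmax(0, pos - w1)
    rate * below
}

#' Simulate a sex-specific SNP marker map
#'
#' Markers are placed uniformly along each chromosome (in non-inverted
#' reference coordinates). Genetic positions integrate a piecewise
#' recombination-rate profile that is zero inside a `suppressWindow`-wide
#' window centred on the planted centromeric array and constant elsewhere,
#' which yields the sigmoidal bp-vs-cM curve of a metacentric chromosome;
#' the female map is `femaleMaleExpansion` times the male map with the same
#' suppression window. Marker flanks are cut from the query genome around
#' the (inversion-mapped) SNP position, so markers inside planted
#' inversions carry the cM of the non-inverted arrangement.
#'
#' @param genome the query genome ([Biostrings::DNAStringSet]) from which
#'   flanks are extracted.
#' @param truth a [SimTruth-class] carrying centromere and inversion truth.
#' @param config a [SimConfig-class].
#' @return list with `markers` (the public marker table) and `truth`
#'   (updated with marker truth).
#' @export
simulateMarkerMap <- function(genome, truth, config) {
    k <- config@flankK
    specs <- truth@inversions
    cen <- truth@centromeres
    cen <- cen[cen$family == "centromere", , drop = FALSE]
    gseq <- as.character(genome)
    tabs <- list()
    tr <- list()
    for (i in seq_along(genome)) {
        ch <- names(genome)[i]
        len <- Biostrings::width(genome)[i]
        n <- round(config@markerDensity * len / 1e6)
        if (n < 2L) {
            warning("chromosome ", ch, " received fewer than 2 markers; ",
                    "flagged unanchorable")
            next
        }
        refPos <- sort(sample(seq.int(k, len - k - 1L), n))
        cr <- cen[cen$chrom == ch, , drop = FALSE]
        mid <- if (nrow(cr)) (cr$start[1] + cr$end[1]) / 2 else len / 2
        w0 <- mid - config@suppressWindow / 2
        w1 <- mid + config@suppressWindow / 2
        male <- integratedCm(refPos, len, w0, w1, config@maleChromMap)
        female <- config@femaleMaleExpansion * male
        if (config@inversionMapGaps && nrow(specs)) {
            sp <- specs[specs$chrom == ch, , drop = FALSE]
            for (r in seq_len(nrow(sp))) {
                oe <- if (sp$kind[r] == "double") sp$second_end[r] else sp$end[r]
                inside <- refPos >= sp$start[r] & refPos < oe
                if (any(inside)) {
                    male[inside] <- integratedCm(sp$start[r], len, w0, w1,
                                                 config@maleChromMap)
                    female[inside] <- config@femaleMaleExpansion * male[inside]
                }
            }
        }
        qPos <- mapThroughInversions(refPos, ch, specs)
        s <- gseq[i]
        left <- substring(s, qPos - k + 1L, qPos)
        right <- substring(s, qPos + 1L, qPos + k)
        id <- sprintf("M_%s_%04d", ch, seq_len(n))
        tabs[[ch]] <- data.frame(
            marker_id = id, lg = i, female_cM = female, male_cM = male,
            flank_left = left, flank_right = right, stringsAsFactors = FALSE)
        tr[[ch]] <- data.frame(
            marker_id = id, chrom = ch, ref_bp = refPos, query_bp = qPos,
            female_cM = female, male_cM = male, stringsAsFactors = FALSE)
    }
    markers <- do.call(rbind, tabs)
    rownames(markers) <- NULL
    truth@markers <- do.call(rbind, tr)
    rownames(truth@markers) <- NULL
    list(markers = markers, truth = truth)
}

#' Simulate a full genome pair with contigs, markers and truth
#'
#' Runs the whole generator: reference genome with centromeric arrays,
#' query genome obtained by applying the configured inversions and a
#' uniform substitution divergence, fragmentation of the query into
#' (optionally chimeric) contigs, and the sex-specific marker map. Each
#' stage is driven by a sub-seed derived from `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return list with `reference`, `query`, `contigs`
#'   ([Biostrings::DNAStringSet]s), `markers` (data.frame) and `truth`
#'   (a [SimTruth-class]).
#' @export
simulateGenomePair <- function(config) {
    ref <- simulateReference(config)
    truth <- ref$truth
    specs <- config@inversionSpecs
    truth@inversions <- specs
    query <- applyInversions(ref$genome, specs)
    if (nrow(specs)) {
        cen <- truth@centromeres
        for (r in seq_len(nrow(cen))) {
            p <- mapThroughInversions(c(cen$start[r], cen$end[r] - 1L),
                                      cen$chrom[r], specs)
            cen$q_start[r] <- min(p)
            cen$q_end[r] <- max(p) + 1L
        }
        ## arrays straddling an inversion boundary would not map rigidly;
        ## the default specs avoid this, but warn if it happens
        if (any(cen$q_end - cen$q_start != cen$end - cen$start))
            warning("a planted array straddles an inversion boundary; ",
                    "its query-coordinate truth interval is approximate")
        truth@centromeres <- cen
    } else {
        truth@centromeres$q_start <- truth@centromeres$start
        truth@centromeres$q_end <- truth@centromeres$end
    }
    if (config@snpDivergence > 0) {
        set.seed(subSeed(config@seed, 1L))
        qs <- as.character(query)
        qs <- vapply(qs, function(s) mutate_dna_cpp(s, config@snpDivergence),
                     "", USE.NAMES = FALSE)
        nm <- names(query)
        query <- Biostrings::DNAStringSet(qs)
        names(query) <- nm
    }
    set.seed(subSeed(config@seed, 2L))
    fr <- fragmentIntoContigs(query, truth, config@contigMeanLen,
                              config@chimeraRate)
    truth <- fr$truth
    set.seed(subSeed(config@seed, 3L))
    mm <- simulateMarkerMap(query, truth, config)
    list(reference = ref$genome, query = query, contigs = fr$contigs,
         markers = mm$markers, truth = mm$truth)
}

#' Ordered truth breakpoints of the planted inversions
#'
#' For a single inversion the breakpoints are `start` and `end`; for a
#' serial double they are `start`, the shared/internal boundary and
#' `second_end` (three in total).
#'
#' @param truth a [SimTruth-class].
#' @return data.frame with columns `chrom`, `kind`, `bp`.
#' @export
truthBreakpoints <- function(truth) {
    specs <- truth@inversions
    if (nrow(specs) == 0L)
        return(data.frame(chrom = character(), kind = character(),
                          bp = numeric(), stringsAsFactors = FALSE))
    out <- lapply(seq_len(nrow(specs)), function(i) {
        r <- specs[i, ]
        bp <- if (r$kind == "double") c(r$start, r$end, r$second_end)
              else c(r$start, r$end)
        data.frame(chrom = r$chrom, kind = r$kind, bp = bp,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' @describeIn truthBreakpoints accessor for the planted inversion specs.
#' @export
truthInversions <- function(truth) truth@inversions

#' @describeIn truthBreakpoints accessor for planted array intervals.
#' @export
truthCentromeres <- function(truth) truth@centromeres

#' @describeIn truthBreakpoints accessor for contig source intervals.
#' @export
truthContigs <- function(truth) truth@contigs

#' @describeIn truthBreakpoints accessor for marker truth.
#' @export
truthMarkers <- function(truth) truth@markers

#' Write / read simulation truth as JSON
#'
#' @param truth a [SimTruth-class].
#' @param path output path.
#' @return `path` invisibly ([writeTruth()]); a [SimTruth-class]
#'   ([readTruth()]).
#' @export
writeTruth <- function(truth, path) {
    jsonlite::write_json(
        list(chromLengths = as.list(truth@chromLengths),
             inversions = truth@inversions,
             centromeres = truth@centromeres,
             contigs = truth@contigs,
             markers = truth@markers),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    asDf <- function(d) if (is.data.frame(d)) d else as.data.frame(d)
    new("SimTruth", chromLengths = unlist(x$chromLengths),
        inversions = asDf(x$inversions), centromeres = asDf(x$centromeres),
        contigs = asDf(x$contigs), markers = asDf(x$markers))
}
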