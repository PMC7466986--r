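## chromosome_builder: place markers on contigs by flanking sequence,
## assign contigs to linkage groups, break chimeras, order and orient by
## cM, and emit chromosome FASTA + AGP.

#' Place markers on contigs by exact flanking-sequence search
#'
#' The concatenation `flank_left + flank_right` (the SNP site sits at the
#' junction) is searched exactly on both strands of every contig. Exactly
#' one hit places the marker at the junction coordinate; more than one hit
#' marks it `ambiguous`. Markers with no exact hit fall back to a seeded
#' search (seed = leftmost `minFlankK`-mer of the concatenated flank)
#' tolerating up to `maxMismatch` mismatches over the full flank, else they
#' are `absent`.
#'
#' @param contigs a [Biostrings::DNAStringSet].
#' @param markers data.frame with `marker_id`, `lg`, `female_cM`, `male_cM`,
#'   `flank_left`, `flank_right`.
#' @param minFlankK minimum flank/seed length in bp (default 31).
#' @param maxMismatch mismatches tolerated by the seeded fallback (default 2).
#' @return data.frame of placements: `marker_id`, `contig_id`, `position`
#'   (0-based bp of the SNP site on the contig), `strand`, `lg`,
#'   `female_cM`, `male_cM`, `status` (`placed`/`ambiguous`/`absent`),
#'   `reason`.
#' @export
placeMarkers <- function(contigs, markers, minFlankK = 31L, maxMismatch = 2L) {
    pattern <- paste0(markers$flank_left, markers$flank_right)
    lw <- nchar(markers$flank_left)
    w <- nchar(pattern)
    n <- nrow(markers)
    hits <- vector("list", n) # each: data.frame(contig_id, start0, strand)

    emptyFlank <- nchar(markers$flank_left) == 0L |
        nchar(markers$flank_right) == 0L
    tooShort <- !emptyFlank &
        (nchar(markers$flank_left) < minFlankK |
         nchar(markers$flank_right) < minFlankK)
    if (any(tooShort))
        warning(sum(tooShort), " marker(s) have flanks shorter than ",
                minFlankK, " bp")
    clean <- !emptyFlank & grepl("^[ACGT]+$", pattern)

    searchable <- which(clean)
    if (length(searchable)) {
        ws <- w[searchable]
        if (length(unique(ws)) == 1L) {
            idxGroups <- list(searchable)
        } else {
            idxGroups <- split(searchable, ws)
        }
        for (grp in idxGroups) {
            pats <- Biostrings::DNAStringSet(pattern[grp])
            pd <- Biostrings::PDict(pats)
            pdrc <- Biostrings::PDict(Biostrings::reverseComplement(pats))
            for (ci in seq_along(contigs)) {
                cid <- names(contigs)[ci]
                for (strand in c("+", "-")) {
                    m <- Biostrings::matchPDict(
                        if (strand == "+") pd else pdrc, contigs[[ci]])
                    nh <- S4Vectors::elementNROWS(m)
                    for (h in which(nh > 0L)) {
                        st <- Biostrings::startIndex(m)[[h]]
                        mi <- grp[h]
                        hits[[mi]] <- rbind(hits[[mi]], data.frame(
                            contig_id = cid, start0 = st - 1L,
                            strand = strand, stringsAsFactors = FALSE))
                    }
                }
            }
        }
    }

    status <- rep("absent", n)
    reason <- rep("", n)
    contig_id <- rep(NA_character_, n)
    position <- rep(NA_real_, n)
    strandOut <- rep(NA_character_, n)

    nHits <- vapply(hits, function(h) if (is.null(h)) 0L else nrow(h), 1L)
    needFallback <- which(clean & nHits == 0L)
    if (length(needFallback)) {
        cseq <- as.character(contigs)
        for (mi in needFallback) {
            seed <- substr(pattern[mi], 1L, minFlankK)
            if (nchar(seed) < minFlankK) next
            fw <- Biostrings::vmatchPattern(seed, contigs)
            rc <- Biostrings::vmatchPattern(revcompChar(seed), contigs)
            cand <- NULL
            prc <- revcompChar(pattern[mi])
            for (ci in seq_along(contigs)) {
                len <- nchar(cseq[ci])
                for (s1 in BiocGenerics::start(fw[[ci]])) {
                    s0 <- s1 - 1L
                    if (s0 + w[mi] > len) next
                    obs <- substr(cseq[ci], s0 + 1L, s0 + w[mi])
                    if (sum(charToRaw(obs) != charToRaw(pattern[mi])) <=
                        maxMismatch)
                        cand <- rbind(cand, data.frame(
                            contig_id = names(contigs)[ci], start0 = s0,
                            strand = "+", stringsAsFactors = FALSE))
                }
                for (s1 in BiocGenerics::start(rc[[ci]])) {
                    s0 <- s1 - 1L + minFlankK - w[mi]
                    if (s0 < 0L || s0 + w[mi] > len) next
                    obs <- substr(cseq[ci], s0 + 1L, s0 + w[mi])
                    if (sum(charToRaw(obs) != charToRaw(prc)) <= maxMismatch)
                        cand <- rbind(cand, data.frame(
                            contig_id = names(contigs)[ci], start0 = s0,
                            strand = "-", stringsAsFactors = FALSE))
                }
            }
            if (!is.null(cand)) hits[[mi]] <- cand
        }
        nHits <- vapply(hits, function(h) if (is.null(h)) 0L else nrow(h), 1L)
    }

    for (mi in seq_len(n)) {
        if (emptyFlank[mi]) { reason[mi] <- "empty flank"; next }
        if (!clean[mi] && nHits[mi] == 0L) {
            reason[mi] <- "ambiguity codes in flank"; next
        }
        if (nHits[mi] == 0L) { reason[mi] <- "no hit"; next }
        if (nHits[mi] > 1L) { status[mi] <- "ambiguous"; next }
        h <- hits[[mi]]
        status[mi] <- "placed"
        contig_id[mi] <- h$contig_id
        strandOut[mi] <- h$strand
        position[mi] <- if (h$strand == "+") h$start0 + lw[mi]
                        else h$start0 + (w[mi] - 1L - lw[mi])
    }

    data.frame(marker_id = markers$marker_id, contig_id = contig_id,
               position = position, strand = strandOut, lg = markers$lg,
               female_cM = markers$female_cM, male_cM = markers$male_cM,
               status = status, reason = reason, stringsAsFactors = FALSE)
}

#' Assign contigs to linkage groups by marker vote
#'
#' The linkage group is the modal LG among a contig's placed markers (ties
#' broken toward the smaller LG). A contig is flagged chimeric when at
#' least two LGs each reach `minVotes` markers; a single discordant marker
#' is treated as placement noise.
#'
#' @param placements output of [placeMarkers()].
#' @param contigs optional [Biostrings::DNAStringSet]; if given, contigs
#'   with no placed markers are included with `lg = NA`.
#' @param minVotes markers required for an LG to count (default 2).
#' @return data.frame: `contig_id`, `lg`, `n_markers`, `mean_female_cM`,
#'   `mean_male_cM`, `is_chimeric`, `discordant_lgs` (comma-separated).
#' @export
assignContigs <- function(placements, contigs = NULL, minVotes = 2L) {
    pl <- placements[placements$status == "placed", , drop = FALSE]
    ids <- unique(pl$contig_id)
    rows <- lapply(ids, function(cid) {
        sub <- pl[pl$contig_id == cid, , drop = FALSE]
        votes <- table(sub$lg)
        modal <- as.integer(names(votes)[which.max(votes)])
        strong <- as.integer(names(votes)[votes >= minVotes])
        chim <- length(strong) >= 2L
        data.frame(contig_id = cid, lg = modal, n_markers = nrow(sub),
                   mean_female_cM = mean(sub$female_cM),
                   mean_male_cM = mean(sub$male_cM),
                   is_chimeric = chim,
                   discordant_lgs = if (chim)
                       paste(sort(strong), collapse = ",") else "",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(contigs)) {
        missing <- setdiff(names(contigs), ids)
        if (length(missing)) {
            out <- rbind(out, data.frame(
                contig_id = missing, lg = NA_integer_, n_markers = 0L,
                mean_female_cM = NA_real_, mean_male_cM = NA_real_,
                is_chimeric = FALSE, discordant_lgs = "",
                stringsAsFactors = FALSE))
        }
    }
    rownames(out) <- NULL
    out
}

#' Break chimeric contigs at the marker-discordance midpoint
#'
#' For each contig flagged chimeric with exactly two LGs, marker positions
#' are partitioned into two segments (trying every split point and both LG
#' orders) to minimize LG discordance. The contig is split at the floor of
#' the midpoint between the last marker of the 5' run and the first marker
#' of the 3' run; children are named `<id>_a` and `<id>_b` and placements
#' are re-coordinated. If the best partition still misassigns more than
#' `maxDiscordance` of the markers (interleaved LGs), the contig is dropped
#' from anchoring with a warning.
#'
#' @param contigs a [Biostrings::DNAStringSet].
#' @param placements output of [placeMarkers()].
#' @param assignments output of [assignContigs()].
#' @param minVotes as in [assignContigs()], used to recompute assignments.
#' @param maxDiscordance maximum tolerated fraction of misassigned markers
#'   after the best two-segment split (default 0.1).
#' @return list: `contigs`, `placements`, `assignments` (all updated),
#'   `broken` (data.frame `contig_id`, `split`), `dropped` (contig ids).
#' @export
breakChimeras <- function(contigs, placements, assignments, minVotes = 2L,
                          maxDiscordance = 0.1) {
    chim <- assignments$contig_id[assignments$is_chimeric]
    broken <- data.frame(contig_id = character(), split = numeric(),
                         stringsAsFactors = FALSE)
    dropped <- character()
    for (cid in chim) {
        lgs <- as.integer(strsplit(
            assignments$discordant_lgs[assignments$contig_id == cid],
            ",")[[1]])
        if (length(lgs) != 2L) {
            warning("chimeric contig ", cid, " involves ", length(lgs),
                    " linkage groups; dropped from anchoring")
            dropped <- c(dropped, cid)
            next
        }
        sub <- placements[placements$status == "placed" &
                          placements$contig_id == cid, , drop = FALSE]
        sub <- sub[order(sub$position), , drop = FALSE]
        nm <- nrow(sub)
        best <- list(disc = Inf, t = NA, left = NA)
        for (t in seq_len(nm - 1L)) {
            for (leftLg in lgs) {
                rightLg <- setdiff(lgs, leftLg)
                disc <- sum(sub$lg[seq_len(t)] != leftLg) +
                        sum(sub$lg[seq.int(t + 1L, nm)] != rightLg)
                if (disc < best$disc) best <- list(disc = disc, t = t,
                                                   left = leftLg)
            }
        }
        if (best$disc / nm > maxDiscordance) {
            warning("chimeric contig ", cid, " has interleaved linkage ",
                    "groups (best split misassigns ",
                    sprintf("%.0f%%", 100 * best$disc / nm),
                    "); dropped from anchoring")
            dropped <- c(dropped, cid)
            next
        }
        split <- floor((sub$position[best$t] + sub$position[best$t + 1L]) / 2)
        len <- Biostrings::width(contigs)[names(contigs) == cid]
        childA <- paste0(cid, "_a")
        childB <- paste0(cid, "_b")
        seqs <- as.character(contigs)
        newSeqs <- c(seqs[names(contigs) != cid],
                     stats::setNames(c(substr(seqs[cid], 1L, split),
                                       substr(seqs[cid], split + 1L, len)),
                                     c(childA, childB)))
        contigs <- Biostrings::DNAStringSet(newSeqs)
        onCid <- !is.na(placements$contig_id) & placements$contig_id == cid
        isLeft <- onCid & placements$position < split
        isRight <- onCid & placements$position >= split
        placements$contig_id[isLeft] <- childA
        placements$contig_id[isRight] <- childB
        placements$position[isRight] <- placements$position[isRight] - split
        broken <- rbind(broken, data.frame(contig_id = cid, split = split,
                                           stringsAsFactors = FALSE))
    }
    if (length(dropped)) {
        drop <- !is.na(placements$contig_id) & placements$contig_id %in% dropped
        placements$status[drop] <- "absent"
        placements$reason[drop] <- "contig dropped (interleaved chimera)"
        placements$contig_id[drop] <- NA_character_
        contigs <- contigs[!names(contigs) %in% dropped]
    }
    assignments <- assignContigs(placements, contigs, minVotes = minVotes)
    list(contigs = contigs, placements = placements,
         assignments = assignments, broken = broken, dropped = dropped)
}

#' Order and orient contigs within each linkage group
#'
#' Contigs are sorted by the mean female cM of their markers (tie-breaks:
#' mean male cM, then contig id). Orientation is the sign of the Kendall
#' rank correlation between marker bp and female cM (male cM when the
#' female positions are all tied); orientations asserted only when
#' `|tau| >= minTau` and at least two distinct cM values exist, otherwise
#' the contig is flagged `?` (emitted as `+`).
#'
#' @param assignments output of [assignContigs()] (chimeras excluded here).
#' @param placements output of [placeMarkers()].
#' @param contigLengths named vector of contig lengths in bp.
#' @param gapLen gap in bp between consecutive contigs (default 500).
#' @param minTau minimum `|tau|` to assert an orientation (default 0.5).
#' @return named list of [ChromosomeBuild-class] objects, one per LG.
#' @export
orderAndOrient <- function(assignments, placements, contigLengths,
                           gapLen = 500L, minTau = 0.5) {
    asg <- assignments[!assignments$is_chimeric & !is.na(assignments$lg), ,
                       drop = FALSE]
    pl <- placements[placements$status == "placed", , drop = FALSE]
    builds <- list()
    for (lg in sort(unique(asg$lg))) {
        sub <- asg[asg$lg == lg, , drop = FALSE]
        o <- order(sub$mean_female_cM, sub$mean_male_cM, sub$contig_id)
        sub <- sub[o, , drop = FALSE]
        orientation <- character(nrow(sub))
        for (i in seq_len(nrow(sub))) {
            mk <- pl[pl$contig_id == sub$contig_id[i], , drop = FALSE]
            cm <- mk$female_cM
            if (length(unique(cm)) < 2L) cm <- mk$male_cM
            if (nrow(mk) < 2L || length(unique(cm)) < 2L) {
                orientation[i] <- "?"
                next
            }
            tau <- suppressWarnings(
                cor(mk$position, cm, method = "kendall"))
            orientation[i] <- if (is.na(tau) || abs(tau) < minTau) "?"
                              else if (tau > 0) "+" else "-"
        }
        comp <- data.frame(
            contig_id = sub$contig_id, orientation = orientation,
            flagged = orientation == "?",
            length = as.numeric(contigLengths[sub$contig_id]),
            mean_female_cM = sub$mean_female_cM, stringsAsFactors = FALSE)
        total <- if (nrow(comp)) sum(comp$length) +
                     as.numeric(gapLen) * (nrow(comp) - 1L) else 0
        builds[[lgName(lg)]] <- new("ChromosomeBuild", lg = as.integer(lg),
                                    components = comp,
                                    gapLen = as.integer(gapLen),
                                    totalLength = total)
    }
    if (length(builds) == 0L)
        warning("no linkage group received any contig")
    builds
}

#' Concatenate a ChromosomeBuild into a chromosome sequence and AGP rows
#'
#' Contigs are joined in build order, `-` components reverse-complemented
#' (`?` emitted as `+`), with `gapLen` N bases between consecutive contigs.
#'
#' @param build a [ChromosomeBuild-class].
#' @param contigs a [Biostrings::DNAStringSet] holding every component.
#' @param gapLen override of the build's gap length.
#' @return list: `sequence` (single-element DNAStringSet named `LGnn`),
#'   `agp` (data.frame in [validateAgp()] layout).
#' @export
concatenateBuild <- function(build, contigs, gapLen = NULL) {
    if (is.null(gapLen)) gapLen <- build@gapLen
    comp <- build@components
    missing <- setdiff(comp$contig_id, names(contigs))
    if (length(missing))
        stop("missing contig sequence(s): ", paste(missing, collapse = ", "))
    obj <- lgName(build@lg)
    segs <- character(0)
    agp <- NULL
    pos <- 0
    for (i in seq_len(nrow(comp))) {
        if (i > 1L && gapLen > 0L) {
            segs <- c(segs, strrep("N", gapLen))
            agp <- rbind(agp, data.frame(
                object_id = obj, object_start = pos + 1, object_end = pos + gapLen,
                component_type = "gap", component_id = "",
                component_start = NA_real_, component_end = NA_real_,
                orientation = "?", stringsAsFactors = FALSE))
            pos <- pos + gapLen
        }
        cid <- comp$contig_id[i]
        s <- as.character(contigs[[cid]])
        ori <- comp$orientation[i]
        if (ori == "-") s <- revcompChar(s)
        len <- nchar(s)
        segs <- c(segs, s)
        agp <- rbind(agp, data.frame(
            object_id = obj, object_start = pos + 1, object_end = pos + len,
            component_type = "contig", component_id = cid,
            component_start = 1, component_end = len,
            orientation = ori, stringsAsFactors = FALSE))
        pos <- pos + len
    }
    out <- Biostrings::DNAStringSet(paste(segs, collapse = ""))
    names(out) <- obj
    validateAgp(agp)
    list(sequence = out, agp = agp)
}

#' Anchoring summary statistics
#'
#' @param builds list of [ChromosomeBuild-class] objects.
#' @param contigs the full contig set ([Biostrings::DNAStringSet]).
#' @param assignments output of [assignContigs()].
#' @return list: `n_contigs_anchored`, `anchored_bp`,
#'   `fraction_of_assembly`, `mean_markers_per_contig`,
#'   `n_contigs_lt5_markers`.
#' @export
anchoringStats <- function(builds, contigs, assignments) {
    comp <- do.call(rbind, lapply(builds, function(b) b@components))
    anchored <- if (is.null(comp)) character() else comp$contig_id
    abp <- if (is.null(comp)) 0 else sum(comp$length)
    tot <- sum(as.numeric(Biostrings::width(contigs)))
    mk <- assignments$n_markers[assignments$contig_id %in% anchored]
    list(n_contigs_anchored = length(anchored),
         anchored_bp = abp,
         fraction_of_assembly = abp / tot,
         mean_markers_per_contig = if (length(mk)) mean(mk) else NA_real_,
         n_contigs_lt5_markers = sum(mk < 5L))
}

#' Run the full linkage-map anchoring pipeline
#'
#' Places markers, assigns contigs to LGs, breaks chimeras, orders/orients
#' and concatenates into chromosome sequences, and maps the placed markers
#' into chromosome coordinates.
#'
#' @inheritParams placeMarkers
#' @inheritParams assignContigs
#' @inheritParams orderAndOrient
#' @param maxMismatch see [placeMarkers()].
#' @return list: `genome` (DNAStringSet of chromosomes), `agp`, `builds`,
#'   `placements` (contig space), `chromMap` (marker positions on the built
#'   chromosomes: `marker_id`, `chrom`, `bp`, `female_cM`, `male_cM`),
#'   `contigs` (post-breaking), `assignments`, `stats`, `broken`, `dropped`.
#' @export
buildChromosomes <- function(contigs, markers, minFlankK = 31L,
                             maxMismatch = 2L, minVotes = 2L,
                             gapLen = 500L, minTau = 0.5) {
    placements <- placeMarkers(contigs, markers, minFlankK, maxMismatch)
    assignments <- assignContigs(placements, contigs, minVotes)
    br <- breakChimeras(contigs, placements, assignments, minVotes)
    contigs <- br$contigs
    placements <- br$placements
    assignments <- br$assignments
    lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
    builds <- orderAndOrient(assignments, placements, lens, gapLen, minTau)
    seqs <- list()
    agp <- NULL
    offsets <- list()
    for (nm in names(builds)) {
        cb <- concatenateBuild(builds[[nm]], contigs)
        seqs[[nm]] <- cb$sequence
        agp <- rbind(agp, cb$agp)
        ctg <- cb$agp[cb$agp$component_type == "contig", , drop = FALSE]
        offsets[[nm]] <- ctg
    }
    genome <- do.call(c, unname(seqs))
    pl <- placements[placements$status == "placed", , drop = FALSE]
    chromMap <- NULL
    for (nm in names(offsets)) {
        ctg <- offsets[[nm]]
        for (i in seq_len(nrow(ctg))) {
            sub <- pl[pl$contig_id == ctg$component_id[i], , drop = FALSE]
            if (nrow(sub) == 0L) next
            off0 <- ctg$object_start[i] - 1
            clen <- ctg$component_end[i]
            bp <- if (ctg$orientation[i] == "-")
                off0 + (clen - 1 - sub$position) else off0 + sub$position
            chromMap <- rbind(chromMap, data.frame(
                marker_id = sub$marker_id, chrom = nm, bp = bp,
                female_cM = sub$female_cM, male_cM = sub$male_cM,
                stringsAsFactors = FALSE))
        }
    }
    if (!is.null(chromMap))
        chromMap <- chromMap[order(chromMap$chrom, chromMap$bp), ]
    stats <- anchoringStats(builds, contigs, assignments)
    list(genome = genome, agp = agp, builds = builds,
         placements = placements, chromMap = chromMap, contigs = contigs,
         assignments = assignments, stats = stats,
         broken = br$broken, dropped = br$dropped)
}
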