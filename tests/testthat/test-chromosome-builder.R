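## a contig set with markers cut verbatim at known positions
makePlantedMarkers <- function(contigSeqs, positions, k = 31L) {
    rows <- lapply(seq_along(positions), function(i) {
        cid <- names(positions)[i]
        p <- positions[[i]]
        s <- contigSeqs[[cid]]
        data.frame(marker_id = sprintf("m%02d", i), lg = 1L,
                   female_cM = i, male_cM = i,
                   flank_left = substr(s, p - k + 1, p),
                   flank_right = substr(s, p + 1, p + k),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

test_that("markers are placed at the cut position on both strands", {
    set.seed(101)
    s <- randomDna(1000)
    contigs <- Biostrings::DNAStringSet(c(tigA = s))
    mk <- makePlantedMarkers(as.character(contigs),
                             list(tigA = 200, tigA = 500))
    names(mk$marker_id) <- NULL
    pl <- placeMarkers(contigs, mk)
    expect_equal(pl$status, c("placed", "placed"))
    expect_equal(pl$position, c(200, 500))
    expect_equal(pl$strand, c("+", "+"))

    ## the same markers on the reverse-complemented contig: strand -,
    ## coordinate mirrored (checked against a brute-force double-strand scan)
    rcContigs <- Biostrings::DNAStringSet(c(tigA = rcChar(s)))
    plrc <- placeMarkers(rcContigs, mk)
    expect_equal(plrc$status, c("placed", "placed"))
    expect_equal(plrc$strand, c("-", "-"))
    expect_equal(plrc$position, 1000 - 1 - c(200, 500))

    ## flanks planted twice -> ambiguous
    dup <- Biostrings::DNAStringSet(c(tigA = s, tigB = s))
    pld <- placeMarkers(dup, mk)
    expect_equal(pld$status, c("ambiguous", "ambiguous"))

    ## empty flank -> absent with reason
    mk2 <- mk; mk2$flank_left[1] <- ""
    pl2 <- placeMarkers(contigs, mk2)
    expect_equal(pl2$status[1], "absent")
    expect_match(pl2$reason[1], "empty")
})

test_that("seeded fallback tolerates up to two mismatches", {
    set.seed(102)
    s <- randomDna(2000)
    contigs <- Biostrings::DNAStringSet(c(tigA = s))
    mk <- makePlantedMarkers(as.character(contigs), list(tigA = 900))
    ## mutate two bases inside the right flank (outside the 31 bp seed)
    sub <- s
    substr(sub, 910, 910) <- chartr("ACGT", "TGCA", substr(sub, 910, 910))
    substr(sub, 920, 920) <- chartr("ACGT", "TGCA", substr(sub, 920, 920))
    mutated <- Biostrings::DNAStringSet(c(tigA = sub))
    mk2 <- makePlantedMarkers(as.character(contigs), list(tigA = 900))
    pl <- placeMarkers(mutated, mk2)
    expect_equal(pl$status, "placed")
    expect_equal(pl$position, 900)

    ## three mismatches exceed the tolerance -> absent
    substr(sub, 925, 925) <- chartr("ACGT", "TGCA", substr(sub, 925, 925))
    pl3 <- placeMarkers(Biostrings::DNAStringSet(c(tigA = sub)), mk2)
    expect_equal(pl3$status, "absent")
})

test_that("contig LG assignment votes and flags chimeras", {
    pl <- data.frame(
        marker_id = sprintf("m%d", 1:9),
        contig_id = c(rep("pure", 3), rep("chim", 5), "noisy"),
        position = c(1, 2, 3, 1, 2, 3, 4, 5, 1) * 100,
        strand = "+",
        lg = c(3L, 3L, 3L, 1L, 1L, 1L, 2L, 2L, 5L),
        female_cM = 1, male_cM = 1, status = "placed", reason = "",
        stringsAsFactors = FALSE)
    asg <- assignContigs(pl, minVotes = 2L)
    pure <- asg[asg$contig_id == "pure", ]
    expect_equal(pure$lg, 3L)
    expect_false(pure$is_chimeric)
    chim <- asg[asg$contig_id == "chim", ]
    expect_true(chim$is_chimeric)
    expect_equal(chim$discordant_lgs, "1,2")

    ## a singleton discordant marker is placement noise, not a chimera
    pl2 <- pl[pl$contig_id == "chim", ]
    pl2$lg <- c(1L, 1L, 1L, 2L, 1L)
    asg2 <- assignContigs(pl2, minVotes = 2L)
    expect_false(asg2$is_chimeric)
    expect_equal(asg2$lg, 1L)
})

test_that("chimeras split at the discordance midpoint; interleaves drop", {
    set.seed(103)
    s <- randomDna(10000)
    contigs <- Biostrings::DNAStringSet(c(chim = s))
    pl <- data.frame(
        marker_id = c("a", "b", "c"), contig_id = "chim",
        position = c(1000, 2000, 8000), strand = "+",
        lg = c(1L, 1L, 2L), female_cM = c(1, 2, 50), male_cM = c(1, 2, 40),
        status = "placed", reason = "", stringsAsFactors = FALSE)
    asg <- assignContigs(pl, contigs, minVotes = 1L)
    expect_true(asg$is_chimeric[asg$contig_id == "chim"])
    br <- breakChimeras(contigs, pl, asg, minVotes = 1L)
    expect_equal(br$broken$split, 5000)
    expect_setequal(names(br$contigs), c("chim_a", "chim_b"))
    expect_equal(unname(Biostrings::width(br$contigs)[
        names(br$contigs) == "chim_a"]), 5000L)
    plA <- br$placements[br$placements$contig_id == "chim_a", ]
    expect_setequal(plA$marker_id, c("a", "b"))
    ## distance to the retained (left) contig end is unchanged
    expect_equal(plA$position, c(1000, 2000))
    ## distance to the retained (right) end is unchanged for the 3' child
    plB <- br$placements[br$placements$contig_id == "chim_b", ]
    expect_equal(5000 - plB$position, 10000 - 8000)

    ## perfectly alternating LGs cannot be split cleanly
    pl2 <- data.frame(
        marker_id = sprintf("m%d", 1:8), contig_id = "chim",
        position = seq(1000, 8000, by = 1000), strand = "+",
        lg = rep(c(1L, 2L), 4), female_cM = 1:8, male_cM = 1:8,
        status = "placed", reason = "", stringsAsFactors = FALSE)
    asg2 <- assignContigs(pl2, contigs, minVotes = 2L)
    expect_warning(br2 <- breakChimeras(contigs, pl2, asg2, minVotes = 2L),
                   "interleaved")
    expect_equal(br2$dropped, "chim")
})

test_that("contigs order by female cM and orient by Kendall tau sign", {
    pl <- data.frame(
        marker_id = sprintf("m%d", 1:6),
        contig_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
        position = c(100, 900, 100, 900, 100, 900), strand = "+",
        lg = 1L,
        female_cM = c(9, 11, 4, 6, 19, 21),
        male_cM = c(9, 11, 4, 6, 19, 21),
        status = "placed", reason = "", stringsAsFactors = FALSE)
    asg <- assignContigs(pl, minVotes = 1L)
    lens <- c(c1 = 1000, c2 = 1000, c3 = 1000)
    builds <- orderAndOrient(asg, pl, lens)
    comp <- builds[["LG01"]]@components
    expect_equal(comp$contig_id, c("c2", "c1", "c3")) # mean cM 5, 10, 20
    expect_equal(comp$orientation, c("+", "+", "+"))

    ## decreasing cM with bp -> reverse orientation
    pl$female_cM[1:2] <- c(2.0, 1.0)
    pl$male_cM[1:2] <- c(2.0, 1.0)
    asg <- assignContigs(pl, minVotes = 1L)
    builds <- orderAndOrient(asg, pl, lens)
    comp <- builds[["LG01"]]@components
    expect_equal(comp$orientation[comp$contig_id == "c1"], "-")

    ## single distinct cM value -> unorientable, flagged
    pl$female_cM[3:4] <- 5; pl$male_cM[3:4] <- 5
    asg <- assignContigs(pl, minVotes = 1L)
    builds <- orderAndOrient(asg, pl, lens)
    comp <- builds[["LG01"]]@components
    expect_true(comp$flagged[comp$contig_id == "c2"])
    expect_equal(comp$orientation[comp$contig_id == "c2"], "?")
})

test_that("concatenation joins, reverse-complements and gaps correctly", {
    set.seed(104)
    a <- randomDna(100); b <- randomDna(100)
    contigs <- Biostrings::DNAStringSet(c(c1 = a, c2 = b))
    comp <- data.frame(contig_id = c("c1", "c2"),
                       orientation = c("+", "-"), flagged = FALSE,
                       length = c(100, 100), mean_female_cM = c(1, 2),
                       stringsAsFactors = FALSE)
    build <- new("ChromosomeBuild", lg = 1L, components = comp,
                 gapLen = 500L, totalLength = 700)
    out <- concatenateBuild(build, contigs)
    expect_equal(unname(Biostrings::width(out$sequence)), 700L)
    s <- as.character(out$sequence)[[1]]
    expect_equal(substr(s, 1, 100), a)
    expect_equal(substr(s, 101, 600), strrep("N", 500))
    expect_equal(substr(s, 601, 700), rcChar(b))
    expect_silent(validateAgp(out$agp))
    expect_equal(sum(out$agp$object_end[out$agp$component_type == "contig"] -
                     out$agp$object_start[out$agp$component_type == "contig"] +
                     1), 200)

    ## a single-contig linkage group equals its (possibly flipped) contig
    solo <- new("ChromosomeBuild", lg = 2L,
                components = comp[2, ], gapLen = 500L, totalLength = 100)
    out2 <- concatenateBuild(solo, contigs)
    expect_equal(as.character(out2$sequence)[[1]], rcChar(b))

    expect_error(concatenateBuild(build, contigs[1]), "missing contig")
})

test_that("anchoring statistics are computed as defined", {
    contigs <- Biostrings::DNAStringSet(c(
        a = strrep("A", 300), b = strrep("A", 200),
        c = strrep("A", 400), d = strrep("A", 100)))
    comp <- data.frame(contig_id = c("a", "b"), orientation = "+",
                       flagged = FALSE, length = c(300, 200),
                       mean_female_cM = c(1, 2), stringsAsFactors = FALSE)
    builds <- list(LG01 = new("ChromosomeBuild", lg = 1L, components = comp,
                              gapLen = 0L, totalLength = 500))
    asg <- data.frame(contig_id = c("a", "b", "c", "d"), lg = c(1L, 1L, NA, NA),
                      n_markers = c(3L, 5L, 0L, 0L),
                      mean_female_cM = c(1, 2, NA, NA),
                      mean_male_cM = c(1, 2, NA, NA),
                      is_chimeric = FALSE, discordant_lgs = "",
                      stringsAsFactors = FALSE)
    st <- anchoringStats(builds, contigs, asg)
    expect_equal(st$n_contigs_anchored, 2L)
    expect_equal(st$fraction_of_assembly, 0.5)
    expect_equal(st$mean_markers_per_contig, 4.0)
    expect_equal(st$n_contigs_lt5_markers, 1L)
})

test_that("the full build recovers simulated chromosome structure", {
    cfg <- smallConfig(seed = 43L, chimeraRate = 0.15)
    sim <- simulateGenomePair(cfg)
    bld <- buildChromosomes(sim$contigs, sim$markers)
    tc <- truthContigs(sim$truth)
    ## a chimera is detectable when each joined part carries at least
    ## minVotes (2) markers; a single-marker part is indistinguishable
    ## from placement noise under the voting rule
    tm <- truthMarkers(sim$truth)
    partMarkers <- vapply(seq_len(nrow(tc)), function(i)
        sum(tm$chrom == tc$chrom[i] & tm$query_bp >= tc$start[i] &
            tm$query_bp < tc$end[i]), 1L)
    detectable <- unique(tc$contig_id[tc$chimeric])
    detectable <- detectable[vapply(detectable, function(id)
        all(partMarkers[tc$contig_id == id] >= 2L), TRUE)]
    handled <- c(bld$broken$contig_id, bld$dropped)
    expect_gt(length(detectable), 0L)
    expect_setequal(intersect(detectable, handled), detectable)
    ## no clean contig is ever broken
    planted <- unique(tc$contig_id[tc$chimeric])
    expect_length(setdiff(handled, planted), 0L)

    ## each child of a broken simulated chimera maps to one chromosome:
    ## its markers all agree on a single linkage group
    for (cid in bld$broken$contig_id) {
        for (child in paste0(cid, c("_a", "_b"))) {
            lgs <- bld$placements$lg[bld$placements$contig_id == child &
                                     bld$placements$status == "placed"]
            expect_length(unique(lgs), 1L)
        }
    }

    ## marker cM is non-decreasing along every emitted chromosome
    ## (modulo the rare misplaced marker; require 99%)
    cm <- bld$chromMap
    frac <- unlist(lapply(split(cm, cm$chrom), function(d) {
        d <- d[order(d$bp), ]
        diff(d$female_cM) >= -1e-9
    }))
    expect_gt(mean(frac), 0.99)

    ## AGP components of each object tile to the emitted length
    for (nm in names(bld$builds)) {
        sub <- bld$agp[bld$agp$object_id == nm, ]
        expect_equal(max(sub$object_end),
                     unname(Biostrings::width(bld$genome)[
                         names(bld$genome) == nm]))
    }
    expect_silent(validateAgp(bld$agp))
    expect_gt(bld$stats$fraction_of_assembly, 0.9)
})
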