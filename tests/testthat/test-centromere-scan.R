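test_that("exact tandems are detected at the configured period range", {
    g <- c(chr = strrep("ACGT", 50))
    expect_equal(nrow(detectTandemArrays(g)), 0L) # period 4 < minPeriod 50
    arr <- detectTandemArrays(g, minPeriod = 4L, seedK = 8L)
    expect_equal(nrow(arr), 1L)
    expect_equal(arr$period, 4L)
    expect_equal(arr$copy_number, 50, tolerance = 0.03)
    expect_equal(arr$consensus, "ACGT")
})

test_that("a planted mutated satellite array is recovered", {
    set.seed(401)
    spec <- CentromereSpec(copiesPerArray = 20L)
    element <- centromereElement(spec)
    copies <- vapply(1:20, function(i)
        chromforge:::mutate_dna_cpp(element, 0.02), "")
    bg <- randomDna(30000, gc = 0.46)
    s <- paste0(substr(bg, 1, 10000), paste(copies, collapse = ""),
                substr(bg, 10001, 30000))
    arr <- detectTandemArrays(c(chr = s))
    expect_equal(nrow(arr), 1L)
    expect_true(arr$period %in% c(86:90, 255:261))
    ## the detected array covers the planted interval (within one period)
    expect_lte(arr$start, 10000 + arr$period)
    expect_gte(arr$end, 10000 + 20 * 258 - arr$period)
    expect_gt(arr$at_fraction, 0.60)
    expect_gt(arr$mean_identity, 0.9)
})

test_that("random sequence contains no multi-copy tandem arrays", {
    set.seed(402)
    s <- randomDna(10000)
    arr <- detectTandemArrays(c(chr = s))
    expect_equal(sum(arr$copy_number >= 3), 0L)
    ## brute-force: no 15-mer recurrence chain of length >= 3 at any lag
    v <- strsplit(s, "")[[1]]
    n <- length(v)
    chains <- 0L
    for (p in 50:600) {
        m <- v[1:(n - p)] == v[(p + 1):n]
        r <- rle(m)
        long <- which(r$values & r$lengths >= 15L)
        if (!length(long)) next
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        seedPos <- unlist(lapply(long, function(i) starts[i]:(ends[i] - 14L)))
        if (any((seedPos + p) %in% seedPos)) chains <- chains + 1L
    }
    expect_equal(chains, 0L)
})

test_that("TRF .dat import maps rows to internal coordinates", {
    f <- withr::local_tempfile(fileext = ".dat")
    cons <- paste(rep("AT", 129), collapse = "")
    writeLines(c(
        "Tandem Repeats Finder Program written by some authors",
        "",
        "Sequence: chrTest some description",
        "",
        "Parameters: 2 7 7 80 10 50 500",
        "",
        sprintf("101 358 258 1.0 258 95 0 200 30 20 30 20 1.9 %s %s",
                cons, cons),
        "bogus row that should be ignored silently"), f)
    arr <- parseTrfDat(f)
    expect_equal(nrow(arr), 1L)
    expect_equal(arr$chrom, "chrTest")
    expect_equal(arr$start, 100) # 1-based inclusive -> 0-based half-open
    expect_equal(arr$end, 358)
    expect_equal(arr$period, 258L)
    expect_equal(arr$mean_identity, 0.95)
    expect_equal(arr$at_fraction, 1)

    ## malformed numeric row -> skipped with warning
    writeLines(c("Sequence: chr1", "12 34 56"), f)
    expect_warning(arr2 <- parseTrfDat(f), "malformed")
    expect_equal(nrow(arr2), 0L)

    file.create(f2 <- withr::local_tempfile(fileext = ".dat"))
    expect_equal(nrow(parseTrfDat(f2)), 0L)
})

test_that("the candidate filter applies strict AT and length bounds", {
    mk <- function(period, at) data.frame(
        chrom = "c", start = 0, end = 10 * period, period = period,
        copy_number = 10, consensus = strrep("A", period),
        at_fraction = at, mean_identity = 1, stringsAsFactors = FALSE)
    expect_equal(nrow(filterCandidates(mk(82L, 0.60))), 0L) # 60.0% AT fails
    expect_equal(nrow(filterCandidates(mk(80L, 0.70))), 0L) # 80 bp fails
    expect_equal(nrow(filterCandidates(mk(88L, 0.70))), 1L)
    ## monotone: tightening thresholds never grows the kept set
    arrs <- rbind(mk(88L, 0.70), mk(120L, 0.65), mk(90L, 0.61))
    n1 <- nrow(filterCandidates(arrs, atMin = 0.60, unitMinLen = 80L))
    n2 <- nrow(filterCandidates(arrs, atMin = 0.64, unitMinLen = 80L))
    n3 <- nrow(filterCandidates(arrs, atMin = 0.64, unitMinLen = 100L))
    expect_true(n1 >= n2 && n2 >= n3)
})

test_that("family clustering respects identity, rotation and strand", {
    set.seed(403)
    cons <- randomDna(88)
    mk <- function(consensus, chrom = "c1") data.frame(
        chrom = chrom, start = 0, end = 880, period = nchar(consensus),
        copy_number = 10, consensus = consensus,
        at_fraction = 0.7, mean_identity = 1, stringsAsFactors = FALSE)

    same <- rbind(mk(cons), mk(cons, "c2"))
    cl <- clusterFamilies(same)
    expect_equal(nrow(cl$families), 1L)
    expect_equal(cl$families$n_members, 2L)
    expect_equal(cl$families$n_chroms, 2L)

    ## 10 of 88 positions differ: 88.6% identity -> two families at 0.95
    far <- cons
    idx <- 1:10
    for (i in idx) substr(far, i, i) <- chartr("ACGT", "CGTA",
                                               substr(far, i, i))
    cl2 <- clusterFamilies(rbind(mk(cons), mk(far, "c2")))
    expect_equal(nrow(cl2$families), 2L)

    ## a rotated and a reverse-complemented copy join the founder family
    rot <- paste0(substr(cons, 41, 88), substr(cons, 1, 40))
    cl3 <- clusterFamilies(rbind(mk(cons), mk(rot, "c2"),
                                 mk(rcChar(cons), "c3")))
    expect_equal(nrow(cl3$families), 1L)
    expect_equal(cl3$families$n_chroms, 3L)
})

test_that("occurrence counting is exact and matches brute force", {
    set.seed(404)
    cons <- randomDna(258, gc = 0.3)
    bg <- randomDna(20000)
    pos <- c(1000, 3000, 6000, 9000, 12000, 15000, 18000)
    s <- bg
    for (i in seq_along(pos)) {
        p <- if (i %% 2 == 0) rcChar(cons) else cons
        substr(s, pos[i] + 1, pos[i] + 258) <- p
    }
    g <- c(chr = s)
    co <- countOccurrences(g, cons)
    expect_equal(co$count, 7L)
    expect_equal(co$positions$start, pos)
    expect_equal(co$positions$strand, c("+", "-", "+", "-", "+", "-", "+"))

    ## genome equal to the consensus itself -> one occurrence
    expect_equal(countOccurrences(c(c = cons), cons)$count, 1L)

    ## a mutated copy is excluded at identity 1.0
    mut <- chromforge:::mutate_dna_cpp(cons, 0.02)
    g2 <- c(chr = paste0(cons, strrep("G", 300), mut))
    expect_equal(countOccurrences(g2, cons, minIdentity = 1.0)$count, 1L)
    expect_equal(countOccurrences(g2, cons, minIdentity = 0.9)$count, 2L)

    ## agreement with the all-offsets brute-force scanner
    set.seed(405)
    noisy <- bg
    for (p in c(2000, 8000, 14000)) {
        substr(noisy, p + 1, p + 258) <-
            chromforge:::mutate_dna_cpp(cons, 0.03)
    }
    gN <- c(chr = noisy)
    impl <- countOccurrences(gN, cons, minIdentity = 0.95)
    oracle <- bruteCountScan(noisy, cons, 0.95)
    expect_equal(impl$count, nrow(oracle))
    expect_equal(impl$positions$start, oracle$start)
    expect_equal(impl$positions$identity, oracle$identity)
})

test_that("density tracks bin and conserve occurrence counts", {
    pos <- data.frame(chrom = "c1", start = seq(0, 9000, by = 1000))
    tr <- densityTrack(pos, c(c1 = 1e5), binSize = 1e4)
    expect_equal(tr$count[1], 10L)
    expect_equal(sum(tr$count), 10L)

    empty <- pos[0, ]
    tr0 <- densityTrack(empty, c(c1 = 1e5), binSize = 1e4)
    expect_true(all(tr0$count == 0L))
    expect_equal(nrow(tr0), 10L)

    expect_error(densityTrack(data.frame(chrom = "c1", start = 2e5),
                              c(c1 = 1e5), 1e4), "beyond")
})

test_that("the unit-spacer-unit sub-structure is detected by self-comparison", {
    set.seed(406)
    el <- centromereElement(CentromereSpec())
    sub <- detectSubunit(el)
    expect_equal(sub$unit_len, 88L)
    expect_equal(sub$spacer_len, 82L)
    expect_equal(sub$unit, substr(el, 1, 88))
    ## a structureless random consensus has no terminal repeat
    expect_null(detectSubunit(randomDna(258)))
})

test_that("the planted family is the unique all-chromosome candidate", {
    cfg <- smallConfig(seed = 61L)
    sim <- simulateGenomePair(cfg)
    arr <- detectTandemArrays(sim$query)
    cen <- centromereCandidates(arr, nChroms = length(sim$query))
    expect_equal(nrow(cen$families), 1L)
    expect_equal(nchar(cen$families$consensus),
                 elementLength(cfg@centromere))
    ## the winning family's members coincide with the planted arrays
    tcen <- truthCentromeres(sim$truth)
    tcen <- tcen[tcen$family == "centromere", ]
    mem <- cen$members
    expect_equal(nrow(mem), nrow(tcen))
    mem <- mem[order(mem$chrom), ]; tcen <- tcen[order(tcen$chrom), ]
    expect_true(all(abs(mem$start - tcen$q_start) <= mem$period + 30))
    expect_true(all(abs(mem$end - tcen$q_end) <= mem$period + 30))
})
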