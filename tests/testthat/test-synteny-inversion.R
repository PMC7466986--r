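test_that("self-comparison yields one full-length forward anchor", {
    set.seed(201)
    s <- randomDna(10000)
    g <- Biostrings::DNAStringSet(c(chr = s))
    an <- findUniqueAnchors(g, g, 21)
    expect_equal(nrow(an), 1L)
    expect_equal(an$strand, "+")
    expect_equal(an$q_start, 0)
    expect_equal(an$q_end, 10000)

    rc <- Biostrings::DNAStringSet(c(chr = rcChar(s)))
    anrc <- findUniqueAnchors(g, rc, 21)
    expect_true(all(anrc$strand == "-"))
    expect_equal(sum(anrc$length), 10000)
})

test_that("anchors reproduce a brute-force unique k-mer dictionary", {
    set.seed(202)
    s <- randomDna(3000)
    mid <- rcChar(substr(s, 1001, 2000))
    t <- paste0(substr(s, 1, 1000), mid, substr(s, 2001, 3000))
    gq <- Biostrings::DNAStringSet(c(chr = s))
    gt <- Biostrings::DNAStringSet(c(chr = t))
    k <- 21
    an <- findUniqueAnchors(gq, gt, k)
    an <- an[order(an$q_start), ]
    ## strand pattern +,-,+ by position (block edges can shift by a base
    ## or two when junction bases happen to extend a match)
    expect_equal(an$strand, c("+", "-", "+"))
    expect_true(all(abs(an$q_start - c(0, 1000, 2000)) <= k))

    seeds <- bruteAnchorSeeds(s, t, k)
    ## every oracle seed must be covered by an anchor of the same strand
    for (i in seq_len(nrow(seeds))) {
        hit <- an$q_start <= seeds$qpos[i] & an$q_end >= seeds$qpos[i] + k &
               an$strand == seeds$strand[i]
        expect_true(any(hit))
    }
    ## and anchor k-mer count equals oracle seed count
    expect_equal(sum(an$length - k + 1), nrow(seeds))
})

test_that("anchors are symmetric under genome exchange", {
    set.seed(203)
    s <- randomDna(2000)
    t <- paste0(substr(s, 1, 800), rcChar(substr(s, 801, 1600)),
                substr(s, 1601, 2000))
    gq <- Biostrings::DNAStringSet(c(a = s))
    gt <- Biostrings::DNAStringSet(c(b = t))
    fwd <- findUniqueAnchors(gq, gt, 21)
    rev <- findUniqueAnchors(gt, gq, 21)
    fwd <- fwd[order(fwd$q_start), ]
    mirrored <- rev[order(rev$t_start), ]
    expect_equal(fwd$q_start, mirrored$t_start)
    expect_equal(fwd$t_start, mirrored$q_start)
    expect_equal(fwd$strand, mirrored$strand)
})

ladder <- function(n = 10L, step = 100, len = 50) {
    data.frame(q_chrom = "q", q_start = (seq_len(n) - 1) * step,
               q_end = (seq_len(n) - 1) * step + len,
               t_chrom = "t", t_start = (seq_len(n) - 1) * step,
               t_end = (seq_len(n) - 1) * step + len,
               strand = "+", length = len, stringsAsFactors = FALSE)
}

test_that("chaining groups a co-linear ladder and splits on big gaps", {
    an <- ladder()
    bl <- chainAnchors(an, maxGap = 1000, minBlockBp = 0, minAnchors = 1)
    expect_equal(nrow(bl), 1L)
    expect_equal(bl$n_anchors, 10L)

    ## displace one anchor beyond maxGap on the target side
    an2 <- ladder()
    an2$t_start[5] <- an2$t_start[5] + 5000
    an2$t_end[5] <- an2$t_end[5] + 5000
    bl2 <- chainAnchors(an2, maxGap = 1000, minBlockBp = 0, minAnchors = 1)
    main <- bl2[which.max(bl2$n_anchors), ]
    expect_equal(main$n_anchors, 9L)
    expect_equal(nrow(bl2), 2L) # the displaced anchor forms its own chain
    oracleW <- brutePartitionWeights(an2, maxGap = 1000)
    expect_equal(sort(bl2$weight_bp, decreasing = TRUE), oracleW)
})

test_that("greedy chain extraction equals brute-force optimal chaining", {
    for (seed in 1:25) {
        set.seed(300 + seed)
        n <- sample(4:12, 1)
        an <- data.frame(
            q_chrom = "q",
            q_start = sort(sample.int(5000, n)),
            t_chrom = "t",
            t_start = sample.int(5000, n),
            strand = sample(c("+", "-"), n, replace = TRUE),
            length = sample.int(400, n), stringsAsFactors = FALSE)
        an$q_end <- an$q_start + an$length
        an$t_end <- an$t_start + an$length
        bl <- chainAnchors(an, maxGap = 800, minBlockBp = 0, minAnchors = 1)
        implW <- sort(bl$weight_bp, decreasing = TRUE)
        oracleW <- brutePartitionWeights(an, maxGap = 800)
        expect_equal(implW, oracleW)
    }
})

test_that("all-forward blocks produce no inversion calls", {
    bl <- data.frame(q_chrom = "LG01",
                     q_start = c(0, 1e5, 2e5), q_end = c(1e5, 2e5, 3e5),
                     t_chrom = "LG01",
                     t_start = c(0, 1e5, 2e5), t_end = c(1e5, 2e5, 3e5),
                     strand = "+", n_anchors = 10L, span_bp = 1e5,
                     stringsAsFactors = FALSE)
    calls <- callInversions(bl)
    expect_equal(nrow(inversionCalls(calls)), 0L)
})

test_that("single and serial-double block signatures are distinguished", {
    ## single inversion: one - run with descending target order
    single <- data.frame(
        q_chrom = "LG05",
        q_start = c(0, 10e5, 13e5, 16e5), q_end = c(10e5, 13e5, 16e5, 20e5),
        t_chrom = "LG05",
        t_start = c(0, 13e5, 10e5, 16e5), t_end = c(10e5, 16e5, 13e5, 20e5),
        strand = c("+", "-", "-", "+"), n_anchors = 10L,
        span_bp = c(10e5, 3e5, 3e5, 4e5), stringsAsFactors = FALSE)
    cs <- callInversions(single)
    expect_equal(inversionCalls(cs)$kind, "single")
    expect_equal(nrow(breakpointIntervals(cs)), 2L)

    ## serial double: two adjacent - runs with ascending target order
    dbl <- single
    dbl$t_start <- c(0, 10e5, 13e5, 16e5)
    dbl$t_end <- c(10e5, 13e5, 16e5, 20e5)
    cd <- callInversions(dbl)
    expect_equal(inversionCalls(cd)$kind, "double")
    iv <- breakpointIntervals(cd)
    expect_equal(nrow(iv), 3L)
    ## breakpoints bracket the three junctions
    expect_true(iv$start[1] <= 10e5 + 1 && iv$end[1] >= 10e5 + 1)
    expect_true(iv$start[2] <= 13e5 + 1 && iv$end[2] >= 13e5 + 1)
    expect_true(iv$start[3] <= 16e5 + 1 && iv$end[3] >= 16e5 + 1)
})

test_that("breakpoint report computes sizes and spans by subtraction", {
    calls <- data.frame(call_id = 1L, chrom = "LGx", kind = "single",
                        stringsAsFactors = FALSE)
    iv <- data.frame(call_id = 1L, chrom = "LGx",
                     start = c(100, 5099), end = c(101, 5100),
                     stringsAsFactors = FALSE)
    cs <- InversionCallSet(calls, iv)
    rep <- reportTable2(cs)
    expect_equal(rep$size_bp, c(1, 1))
    expect_equal(rep$span_mb[1], 0.00) # 4,999 bp rounds to 0.00 Mb
    expect_true(is.na(rep$span_mb[2]))
})

test_that("PAF records become blocks and drive inversion calls", {
    paf <- data.frame(
        query_id = "q", query_len = 3e5,
        query_start = c(0, 1e5, 2e5), query_end = c(1e5, 2e5, 3e5),
        strand = c("+", "-", "+"), target_id = "t", target_len = 3e5,
        target_start = c(0, 1e5, 2e5), target_end = c(1e5, 2e5, 3e5),
        n_matches = 9e4, block_len = 1e5, mapq = 60L,
        stringsAsFactors = FALSE)
    bl <- blocksFromPaf(paf, minBlockBp = 5e4)
    expect_equal(nrow(bl), 3L)
    expect_equal(bl$strand, c("+", "-", "+"))
    cs <- callInversions(bl)
    expect_equal(inversionCalls(cs)$kind, "single")

    ## one 50 kb record -> one block
    one <- paf[1, ]; one$query_end <- 5e4; one$target_end <- 5e4
    expect_equal(nrow(blocksFromPaf(one, minBlockBp = 2e4)), 1L)

    ## two + records separated by 10 kb merge under maxGap 100 kb
    two <- paf[c(1, 3), ]
    two$query_start <- c(0, 11e4); two$query_end <- c(1e5, 2e5)
    two$target_start <- c(0, 11e4); two$target_end <- c(1e5, 2e5)
    merged <- blocksFromPaf(two, minBlockBp = 2e4, maxGap = 1e5)
    expect_equal(nrow(merged), 1L)
    expect_equal(merged$n_anchors, 2L)

    expect_error(blocksFromPaf(paf, queryNames = "other"), "q")
})

test_that("planted inversions are recovered on a small genome pair", {
    cfg <- smallConfig(seed = 51L)
    cfg@inversionSpecs <- defaultInversionSpecs(cfg)
    sim <- simulateGenomePair(cfg)
    an <- findUniqueAnchors(sim$query, sim$reference)
    bl <- chainAnchors(an, maxGap = 5e4, minBlockBp = 1e4)
    cs <- suppressWarnings(callInversions(bl))
    cl <- inversionCalls(cs)
    expect_equal(nrow(cl), 4L)
    expect_equal(sort(table(cl$kind), decreasing = TRUE),
                 sort(table(c("double", rep("single", 3))), decreasing = TRUE))
    tb <- truthBreakpoints(sim$truth)
    iv <- breakpointIntervals(cs)
    for (i in seq_len(nrow(tb))) {
        sub <- iv[iv$chrom == tb$chrom[i], ]
        ## 8 bp slack: junction placement is ambiguous across
        ## coincidentally matching junction bases
        expect_true(any(sub$start - 8 <= tb$bp[i] + 1 &
                        sub$end + 8 >= tb$bp[i] + 1))
    }

    ## finer blocks give breakpoint intervals that are no wider
    bl2 <- chainAnchors(an, maxGap = 5e4, minBlockBp = 2e3)
    iv2 <- breakpointIntervals(suppressWarnings(callInversions(bl2)))
    expect_lte(sum(iv2$size), sum(iv$size))

    ## with an AGP, intervals are annotated with contig context
    bld <- buildChromosomes(sim$contigs, sim$markers)
    ann <- annotateContigContext(cs, bld$agp)
    expect_true(all(ann$contig_context %in%
                    c("within contig", "between contigs")))
})
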