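## Independent brute-force oracles and small fixture builders used across
## the suite. These deliberately avoid the package's own k-mer machinery.

rcChar <- function(x) {
    vapply(x, function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                             "")[[1]]), collapse = ""),
           "", USE.NAMES = FALSE)
}

randomDna <- function(n, gc = 0.5) {
    paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
}

## all k-mer matches between two single-sequence genomes where the k-mer is
## unique (counting both strands) in each; returns per-position seeds
bruteAnchorSeeds <- function(q, t, k) {
    kmersOf <- function(s) substring(s, seq_len(nchar(s) - k + 1L),
                                     seq.int(k, nchar(s)))
    canon <- function(v) pmin(v, rcChar(v))
    qk <- kmersOf(q); tk <- kmersOf(t)
    qc <- canon(qk); tc <- canon(tk)
    qTab <- table(qc); tTab <- table(tc)
    shared <- intersect(names(qTab)[qTab == 1L], names(tTab)[tTab == 1L])
    qi <- match(shared, qc); ti <- match(shared, tc)
    strand <- ifelse(qk[qi] == tk[ti], "+", "-")
    data.frame(qpos = qi - 1L, tpos = ti - 1L, strand = strand,
               stringsAsFactors = FALSE)[order(qi), ]
}

## chain compatibility exactly as documented for chainAnchors()
chainCompat <- function(a, b, maxGap) {
    if (a$strand != b$strand) return(FALSE)
    if (!(b$q_start > a$q_start)) return(FALSE)
    qgap <- b$q_start - a$q_end
    if (qgap < 0 || qgap > maxGap) return(FALSE)
    tgap <- if (a$strand == "+") b$t_start - a$t_end else a$t_start - b$t_end
    tgap >= 0 && tgap <= maxGap
}

## exhaustive maximum-weight co-linear chain over <= ~15 anchors
bruteBestChain <- function(anchors, maxGap) {
    n <- nrow(anchors)
    o <- order(anchors$q_start, anchors$t_start)
    anchors <- anchors[o, , drop = FALSE]
    best <- list(w = -Inf, idx = integer())
    for (mask in seq_len(2^n) - 1L) {
        idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
        if (length(idx) == 0L) next
        ok <- TRUE
        if (length(idx) > 1L) {
            for (j in seq_len(length(idx) - 1L)) {
                if (!chainCompat(anchors[idx[j], ], anchors[idx[j + 1L], ],
                                 maxGap)) { ok <- FALSE; break }
            }
        }
        if (!ok) next
        w <- sum(anchors$length[idx])
        if (w > best$w) best <- list(w = w, idx = idx)
    }
    list(weight = best$w, idx = o[best$idx])
}

## iterated brute-force extraction: the chain-weight multiset of the
## partition, largest first
brutePartitionWeights <- function(anchors, maxGap) {
    weights <- numeric()
    remaining <- anchors
    while (nrow(remaining)) {
        b <- bruteBestChain(remaining, maxGap)
        weights <- c(weights, b$weight)
        remaining <- remaining[-b$idx, , drop = FALSE]
    }
    sort(weights, decreasing = TRUE)
}

## all-offsets ungapped scan of a consensus over one sequence, both
## strands, best-first non-overlapping
bruteCountScan <- function(subject, pattern, minIdentity) {
    L <- nchar(pattern)
    sv <- strsplit(subject, "")[[1]]
    hitsFor <- function(p, strand) {
        pv <- strsplit(p, "")[[1]]
        n <- length(sv) - L + 1L
        if (n < 1L) return(NULL)
        ident <- vapply(seq_len(n), function(s)
            sum(sv[s:(s + L - 1L)] == pv) / L, 1.0)
        keep <- which(ident >= minIdentity)
        if (!length(keep)) return(NULL)
        data.frame(start = keep - 1L, identity = ident[keep],
                   strand = strand, stringsAsFactors = FALSE)
    }
    hits <- rbind(hitsFor(pattern, "+"), hitsFor(rcChar(pattern), "-"))
    if (is.null(hits)) return(data.frame(start = numeric(),
                                         identity = numeric(),
                                         strand = character()))
    hits <- hits[order(-hits$identity, hits$start, hits$strand), ,
                 drop = FALSE]
    taken <- NULL
    for (i in seq_len(nrow(hits))) {
        s <- hits$start[i]
        if (!is.null(taken) && any(taken$start < s + L &
                                   taken$start + L > s)) next
        taken <- rbind(taken, hits[i, , drop = FALSE])
    }
    taken[order(taken$start), , drop = FALSE]
}

## compact simulator config for fast tests
smallConfig <- function(seed = 1L, nChromosomes = 4L, chromLength = 4e5,
                        suppressWindow = 0.2 * chromLength, ...) {
    SimConfig(nChromosomes = nChromosomes, chromLength = chromLength,
              markerDensity = 150, contigMeanLen = 6e4,
              suppressWindow = suppressWindow, nDecoyChroms = 2L,
              centromere = CentromereSpec(copiesPerArray = 10L),
              seed = seed, ...)
}
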