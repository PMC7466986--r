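## recomb_profile: sex-specific map statistics, windowed recombination
## rates, suppressed-region finding, chromosome-morphology classification
## and co-location with centromere-repeat density.

#' Sex-specific linkage-map statistics
#'
#' Per-chromosome map lengths are `max(cM) - min(cM)`; totals sum over
#' chromosomes and the female:male ratio is rounded to one decimal for
#' reporting (full precision in `fm_ratio_raw`).
#'
#' @param points data.frame with `chrom`, `female_cM`, `male_cM` (e.g. the
#'   `chromMap` of [buildChromosomes()], or any marker table with a `chrom`
#'   column).
#' @return list: `female_total_cM`, `male_total_cM`, `fm_ratio`,
#'   `fm_ratio_raw`.
#' @export
#' @examples
#' pts <- data.frame(chrom = "LG01", bp = c(0, 1),
#'                   female_cM = c(0, 1662.7), male_cM = c(0, 1262.3))
#' mapStats(pts)$fm_ratio # 1.3
mapStats <- function(points) {
    perChrom <- split(points, points$chrom)
    small <- names(perChrom)[vapply(perChrom, nrow, 1L) < 2L]
    if (length(small))
        warning("chromosome(s) with fewer than 2 markers excluded: ",
                paste(small, collapse = ", "))
    perChrom <- perChrom[vapply(perChrom, nrow, 1L) >= 2L]
    f <- sum(vapply(perChrom, function(d) max(d$female_cM) - min(d$female_cM),
                    1.0))
    m <- sum(vapply(perChrom, function(d) max(d$male_cM) - min(d$male_cM),
                    1.0))
    if (m == 0) stop("male map total is zero; ratio undefined")
    list(female_total_cM = f, male_total_cM = m,
         fm_ratio = round(f / m, 1), fm_ratio_raw = f / m)
}

#' Windowed recombination rates along a chromosome
#'
#' cM positions are linearly interpolated between flanking markers
#' (constant beyond the outermost markers) and differenced over fixed
#' windows: `rate = (cM(end) - cM(start)) / (binBp / 1e6)` in cM/Mb.
#' Monotonicity violations up to `clampTol` cM are clamped (real-map
#' noise); larger violations are an input error.
#'
#' @param points data.frame with `chrom`, `bp` and the chosen sex's cM
#'   column; a single chromosome's markers.
#' @param binBp window width in bp.
#' @param sex `"female"` or `"male"` (default `"female"`).
#' @param chromLen chromosome length in bp; defaults to the last marker.
#' @param clampTol tolerated cM back-step (default 0.5).
#' @return data.frame: `chrom`, `win_start`, `win_end`, `rate`.
#' @export
windowRates <- function(points, binBp, sex = c("female", "male"),
                        chromLen = NULL, clampTol = 0.5) {
    sex <- match.arg(sex)
    cmcol <- paste0(sex, "_cM")
    stopifnot(length(unique(points$chrom)) == 1L, nrow(points) >= 2L)
    o <- order(points$bp)
    bp <- points$bp[o]
    cm <- points[[cmcol]][o]
    drops <- diff(cm)
    if (any(drops < -clampTol))
        stop("cM decreases by more than ", clampTol,
             " cM along the chromosome; refusing to smooth")
    cm <- cummax(cm)
    if (is.null(chromLen)) chromLen <- max(bp)
    edges <- seq(0, ceiling(chromLen / binBp) * binBp, by = binBp)
    at <- stats::approx(bp, cm, xout = edges, rule = 2, ties = "ordered")$y
    data.frame(chrom = points$chrom[1], win_start = edges[-length(edges)],
               win_end = edges[-1], rate = diff(at) / (binBp / 1e6),
               stringsAsFactors = FALSE)
}

#' Find the recombination-suppressed region of a chromosome
#'
#' The longest maximal run of consecutive windows with rate below
#' `relThreshold` times the chromosome's median windowed rate (ties broken
#' toward the run with the lower mean rate). Returns `NULL` when no window
#' qualifies. Suppression thresholds are conventions, not measured
#' constants; both centromeres and inversion heterozygotes suppress
#' recombination, so a suppressed region is evidence about the centromere,
#' not proof.
#'
#' @param rates data.frame from [windowRates()] (one chromosome).
#' @param relThreshold fraction of the median rate (default 0.2).
#' @param sex label recorded on the region (default `"female"`).
#' @return one-row data.frame `chrom`, `start`, `end`, `mean_rate`, `sex`,
#'   or `NULL`.
#' @export
findSuppressed <- function(rates, relThreshold = 0.2, sex = "female") {
    stopifnot(nrow(rates) >= 3L)
    thr <- relThreshold * median(rates$rate)
    low <- rates$rate < thr
    if (!any(low)) return(NULL)
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    lens <- r$lengths[runs]
    best <- runs[lens == max(lens)]
    if (length(best) > 1L) {
        means <- vapply(best, function(ri)
            mean(rates$rate[starts[ri]:ends[ri]]), 1.0)
        best <- best[which.min(means)]
    }
    i0 <- starts[best]; i1 <- ends[best]
    data.frame(chrom = rates$chrom[1], start = rates$win_start[i0],
               end = rates$win_end[i1],
               mean_rate = mean(rates$rate[i0:i1]), sex = sex,
               stringsAsFactors = FALSE)
}

#' Classify chromosome morphology from the suppressed region
#'
#' Metacentric when the suppressed-region midpoint falls in the central
#' band of the chromosome (default \[0.25, 0.75\] of its length — the
#' sigmoidal-profile case); otherwise non-metacentric; unclassified when
#' no suppressed region was found.
#'
#' @param region one-row data.frame from [findSuppressed()], or `NULL`.
#' @param chromLen chromosome length in bp.
#' @param centralBand numeric length-2 fraction band (default c(0.25, 0.75)).
#' @return list: `class`, `suppressed_midpoint_fraction`.
#' @export
classifyMorphology <- function(region, chromLen,
                               centralBand = c(0.25, 0.75)) {
    if (is.null(region))
        return(list(class = "unclassified",
                    suppressed_midpoint_fraction = NA_real_))
    frac <- (region$start + region$end) / 2 / chromLen
    cls <- if (frac >= centralBand[1] && frac <= centralBand[2])
        "metacentric" else "non_metacentric"
    list(class = cls, suppressed_midpoint_fraction = frac)
}

#' Test co-location of a suppressed region with repeat density
#'
#' TRUE when the midpoint of the maximum-density bin lies within the
#' suppressed region extended by `flankBp` on each side; the signed
#' distance runs from the region midpoint to the peak midpoint.
#'
#' @param region one-row data.frame from [findSuppressed()].
#' @param track density rows for the same chromosome
#'   (from [densityTrack()]).
#' @param flankBp extension of the region on each side; defaults to one
#'   bin width.
#' @return list: `colocated` (logical or `NA`), `distance` (bp).
#' @export
colocalize <- function(region, track, flankBp = NULL) {
    if (nrow(track) == 0L || all(track$count == 0L)) {
        warning("empty density track; co-location undetermined")
        return(list(colocated = NA, distance = NA_real_))
    }
    if (is.null(flankBp)) flankBp <- track$bin_end[1] - track$bin_start[1]
    peak <- which.max(track$count)
    peakMid <- (track$bin_start[peak] + track$bin_end[peak]) / 2
    regionMid <- (region$start + region$end) / 2
    list(colocated = peakMid >= region$start - flankBp &&
             peakMid <= region$end + flankBp,
         distance = peakMid - regionMid)
}

#' Per-chromosome recombination profile and morphology report
#'
#' Runs [windowRates()], [findSuppressed()], [classifyMorphology()] and
#' [colocalize()] for every chromosome of a marker map.
#'
#' @param points data.frame with `chrom`, `bp`, `female_cM`, `male_cM`.
#' @param track full density track from [densityTrack()] (may be `NULL`).
#' @param chromLengths named vector of chromosome lengths.
#' @param binBp window width in bp (default 1e5).
#' @param sex profile sex (default `"female"`, the denser map).
#' @param relThreshold see [findSuppressed()].
#' @param centralBand see [classifyMorphology()].
#' @return data.frame, one row per chromosome: map totals, suppressed
#'   region, morphology class, co-location flag and distance.
#' @export
recombProfile <- function(points, track = NULL, chromLengths,
                          binBp = 1e5, sex = "female",
                          relThreshold = 0.2,
                          centralBand = c(0.25, 0.75)) {
    out <- NULL
    for (ch in names(chromLengths)) {
        sub <- points[points$chrom == ch, , drop = FALSE]
        if (nrow(sub) < 2L) {
            warning("chromosome ", ch, " has fewer than 2 markers; skipped")
            next
        }
        rates <- tryCatch(
            windowRates(sub, binBp, sex, chromLen = chromLengths[[ch]]),
            error = function(e) {
                warning("chromosome ", ch, " skipped: ",
                        conditionMessage(e))
                NULL
            })
        if (is.null(rates)) {
            out <- rbind(out, data.frame(
                chrom = ch,
                female_total_cM = max(sub$female_cM) - min(sub$female_cM),
                male_total_cM = max(sub$male_cM) - min(sub$male_cM),
                sup_start = NA_real_, sup_end = NA_real_,
                class = "unclassified", midpoint_fraction = NA_real_,
                colocated = NA, peak_distance = NA_real_,
                stringsAsFactors = FALSE))
            next
        }
        region <- findSuppressed(rates, relThreshold, sex)
        morph <- classifyMorphology(region, chromLengths[[ch]], centralBand)
        col <- list(colocated = NA, distance = NA_real_)
        if (!is.null(region) && !is.null(track)) {
            tsub <- track[track$chrom == ch, , drop = FALSE]
            col <- suppressWarnings(colocalize(region, tsub))
        }
        out <- rbind(out, data.frame(
            chrom = ch,
            female_total_cM = max(sub$female_cM) - min(sub$female_cM),
            male_total_cM = max(sub$male_cM) - min(sub$male_cM),
            sup_start = if (is.null(region)) NA_real_ else region$start,
            sup_end = if (is.null(region)) NA_real_ else region$end,
            class = morph$class,
            midpoint_fraction = morph$suppressed_midpoint_fraction,
            colocated = col$colocated, peak_distance = col$distance,
            stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
}
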