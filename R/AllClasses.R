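#' @import methods
#' @importFrom stats median cor rexp runif approx
#' @importFrom utils read.delim write.table head tail
#' @useDynLib chromforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Centromeric satellite element specification
#'
#' Describes the unit--spacer--unit tandem element planted by the simulator:
#' two identical direct repeats of `unitLen` bp separated by a `spacerLen` bp
#' spacer (defaults 88 + 82 + 88 = 258 bp), with an AT fraction high enough
#' to pass the centromere-candidate filter (strictly more than 60% AT).
#'
#' @slot unitLen integer, length in bp of each of the two identical sub-units.
#' @slot spacerLen integer, length in bp of the intervening spacer.
#' @slot atFraction numeric in (0, 1], AT fraction of the constructed element.
#' @slot copiesPerArray integer, tandem copies of the element per planted array.
#' @slot positionFraction numeric vector in \[0, 1\]; array midpoint as a
#'   fraction of chromosome length (0.5 = metacentric), recycled over
#'   chromosomes.
#' @slot mutationRate numeric, per-base substitution rate applied
#'   independently to each planted copy.
#' @exportClass CentromereSpec
setClass("CentromereSpec",
    representation(
        unitLen = "integer",
        spacerLen = "integer",
        atFraction = "numeric",
        copiesPerArray = "integer",
        positionFraction = "numeric",
        mutationRate = "numeric"
    )
)

setValidity("CentromereSpec", function(object) {
    msg <- character()
    if (object@unitLen < 1L) msg <- c(msg, "unitLen must be positive")
    if (object@spacerLen < 0L) msg <- c(msg, "spacerLen must be non-negative")
    if (object@atFraction < 0 || object@atFraction > 1)
        msg <- c(msg, "atFraction must be in [0, 1]")
    if (object@copiesPerArray < 2L)
        msg <- c(msg, "copiesPerArray must be at least 2")
    if (any(object@positionFraction < 0) || any(object@positionFraction > 1))
        msg <- c(msg, "positionFraction must be in [0, 1]")
    if (object@mutationRate < 0 || object@mutationRate > 1)
        msg <- c(msg, "mutationRate must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Holds every knob of the synthetic-genome generator: chromosome count and
#' lengths, base composition, planted inversions, centromeric arrays, marker
#' map shape, contig fragmentation and the master seed. All downstream
#' randomness is a deterministic function of `seed`.
#'
#' @slot nChromosomes integer, haploid chromosome number (default 23).
#' @slot chromLengths named numeric vector of chromosome lengths in bp.
#' @slot gcFraction numeric, genome-wide GC fraction for the i.i.d. background.
#' @slot inversionSpecs data.frame of planted inversions (see
#'   [inversionSpecs()]).
#' @slot centromere a [CentromereSpec-class] object.
#' @slot markerDensity numeric, markers per Mb.
#' @slot contigMeanLen numeric, mean contig length in bp (exponential cuts).
#' @slot chimeraRate numeric in \[0, 1\], probability that a contig is a
#'   chimeric join of fragments from two chromosomes.
#' @slot femaleMaleExpansion numeric >= 1, female:male map-length ratio.
#' @slot maleChromMap numeric, male map length per chromosome in cM.
#' @slot suppressWindow numeric, width in bp of the pericentromeric window
#'   in which the recombination rate is zero.
#' @slot snpDivergence numeric, per-base substitution divergence applied to
#'   the derived (query) genome.
#' @slot flankK integer, flank length in bp on each side of a simulated SNP.
#' @slot nDecoyChroms integer, number of chromosomes that additionally carry
#'   a decoy AT-rich tandem array (a repeat family that must fail the
#'   all-chromosomes coverage test).
#' @slot repeatBackground logical, sprinkle a dispersed non-tandem repeat
#'   over the genome (off by default; the background is otherwise i.i.d.).
#' @slot inversionMapGaps logical, collapse marker cM inside planted
#'   inversions to mimic suppressed recombination in inversion heterozygotes.
#' @slot seed integer master seed.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        nChromosomes = "integer",
        chromLengths = "numeric",
        gcFraction = "numeric",
        inversionSpecs = "data.frame",
        centromere = "CentromereSpec",
        markerDensity = "numeric",
        contigMeanLen = "numeric",
        chimeraRate = "numeric",
        femaleMaleExpansion = "numeric",
        maleChromMap = "numeric",
        suppressWindow = "numeric",
        snpDivergence = "numeric",
        flankK = "integer",
        nDecoyChroms = "integer",
        repeatBackground = "logical",
        inversionMapGaps = "logical",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be positive")
    if (length(object@chromLengths) != object@nChromosomes)
        msg <- c(msg, "chromLengths must have one entry per chromosome")
    if (any(object@chromLengths <= 0)) msg <- c(msg, "chromosome lengths must be positive")
    if (object@gcFraction < 0 || object@gcFraction > 1)
        msg <- c(msg, "gcFraction must be in [0, 1]")
    if (object@chimeraRate < 0 || object@chimeraRate > 1)
        msg <- c(msg, "chimeraRate must be in [0, 1]")
    if (object@femaleMaleExpansion < 1)
        msg <- c(msg, "femaleMaleExpansion must be >= 1")
    if (object@markerDensity <= 0) msg <- c(msg, "markerDensity must be positive")
    if (object@contigMeanLen <= 0) msg <- c(msg, "contigMeanLen must be positive")
    if (object@snpDivergence < 0 || object@snpDivergence > 1)
        msg <- c(msg, "snpDivergence must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated genome pair
#'
#' Records everything the simulator planted, so downstream recovery can be
#' scored exactly: inversion breakpoints, centromeric array intervals (in
#' both reference and query coordinates), contig source intervals (with
#' chimera flags) and marker truth. All coordinates are 0-based half-open.
#'
#' @slot chromLengths named numeric vector of chromosome lengths.
#' @slot inversions data.frame of planted inversion intervals.
#' @slot centromeres data.frame of planted array intervals.
#' @slot contigs data.frame of contig source intervals.
#' @slot markers data.frame of marker truth.
#' @exportClass SimTruth
setClass("SimTruth",
    representation(
        chromLengths = "numeric",
        inversions = "data.frame",
        centromeres = "data.frame",
        contigs = "data.frame",
        markers = "data.frame"
    )
)

#' An ordered, oriented set of contigs forming one chromosome
#'
#' AGP-like semantics: `components` lists contigs in emission order with
#' orientation (`+`, `-`, or `?` for unorientable single-marker contigs,
#' emitted as `+` but flagged); consecutive contigs are separated by
#' `gapLen` N bases.
#'
#' @slot lg integer linkage group number.
#' @slot components data.frame with columns `contig_id`, `orientation`,
#'   `flagged`, `length`, `mean_female_cM`.
#' @slot gapLen integer, gap length in bp between consecutive contigs.
#' @slot totalLength numeric, emitted chromosome length.
#' @exportClass ChromosomeBuild
setClass("ChromosomeBuild",
    representation(
        lg = "integer",
        components = "data.frame",
        gapLen = "integer",
        totalLength = "numeric"
    )
)

setValidity("ChromosomeBuild", function(object) {
    n <- nrow(object@components)
    expect <- if (n == 0L) 0 else
        sum(object@components$length) + as.numeric(object@gapLen) * (n - 1L)
    if (!isTRUE(all.equal(expect, object@totalLength)))
        return(sprintf("totalLength (%s) != sum of contigs + gaps (%s)",
                       format(object@totalLength), format(expect)))
    if (n > 0L && !all(object@components$orientation %in% c("+", "-", "?")))
        return("orientation must be one of +, -, ?")
    TRUE
})

#' A set of inversion calls with breakpoint intervals
#'
#' `calls` has one row per rearrangement (`kind` is `single` or `double`);
#' `intervals` holds the ordered breakpoint intervals (2 for a single, 3 for
#' a double) in report coordinates: 1-based `start` with `size = end - start`
#' (the end-exclusive subtraction used by the breakpoint-interval report).
#' `span_mb` is the outer span (last end - first start) / 1e6 rounded to two
#' decimals.
#'
#' @slot calls data.frame with columns `call_id`, `chrom`, `kind`, `span_mb`.
#' @slot intervals data.frame with columns `call_id`, `chrom`, `start`,
#'   `end`, `size`.
#' @exportClass InversionCallSet
setClass("InversionCallSet",
    representation(
        calls = "data.frame",
        intervals = "data.frame"
    )
)

setValidity("InversionCallSet", function(object) {
    msg <- character()
    iv <- object@intervals
    cl <- object@calls
    if (nrow(iv)) {
        if (any(iv$start >= iv$end)) msg <- c(msg, "intervals must have start < end")
        if (any(iv$size != iv$end - iv$start))
            msg <- c(msg, "interval size must equal end - start")
    }
    for (id in cl$call_id) {
        sub <- iv[iv$call_id == id, , drop = FALSE]
        kind <- cl$kind[cl$call_id == id]
        want <- if (kind == "double") 3L else 2L
        if (nrow(sub) != want)
            msg <- c(msg, sprintf("call %s (%s) must have %d intervals, has %d",
                                  id, kind, want, nrow(sub)))
        if (nrow(sub) > 1L && is.unsorted(sub$start))
            msg <- c(msg, sprintf("call %s intervals must be sorted", id))
        if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)]))
            msg <- c(msg, sprintf("call %s intervals must not overlap", id))
    }
    if (length(msg)) msg else TRUE
})
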