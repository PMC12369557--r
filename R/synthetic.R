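#' Constructors for generator configuration objects
#'
#' `brandDesign()` describes one brand's blending design: how many samples
#' and the admissible percentage range of each raw material.  Components
#' not listed are absent (exactly 0%).  `domainShift()` describes the
#' brand-level spectral perturbation layered on top of the mixing model.
#'
#' @param brand brand label.
#' @param nSamples number of samples to draw.
#' @param componentRanges named list of `c(min, max)` percent ranges.
#' @param analyte name of the component whose percentage is the regression
#'   target; defaults to `"tobacco_silk"`.
#' @param silkVariant identifier of a brand-specific analyte endmember, or
#'   `""` for the shared one.
#' @return `brandDesign()`: a [BrandDesign-class]; `domainShift()`: a
#'   [DomainShift-class].
#' @examples
#' brandDesign("B2", 199, list(tobacco_silk = c(75, 100),
#'                             fermented_cut_stem = c(0, 25)))
#' @export
brandDesign <- function(brand, nSamples, componentRanges,
                        analyte = "tobacco_silk", silkVariant = "") {
    new("BrandDesign", brand = as.character(brand),
        nSamples = stopifnotScalarCount(nSamples, "nSamples"),
        componentRanges = componentRanges, analyte = analyte,
        silkVariant = as.character(silkVariant))
}

#' @rdname brandDesign
#' @param offset additive offset (absorbance units).
#' @param slope baseline tilt (absorbance per cm^-1, applied to
#'   `w - mean(w)`).
#' @param gain multiplicative gain (> 0).
#' @param noiseSD i.i.d. Gaussian noise SD per grid point (absorbance).
#' @export
domainShift <- function(offset = 0, slope = 0, gain = 1, noiseSD = 0) {
    new("DomainShift", offset = as.numeric(offset), slope = as.numeric(slope),
        gain = as.numeric(gain), noiseSD = as.numeric(noiseSD))
}

# Default Gaussian band tables.  Centers sit on the absorption peaks
# characteristic of plant-material NIR spectra (C-H, N-H, O-H overtone and
# combination bands); troughs fall in the gaps between bands.  Amplitudes
# differ per component so that blending proportion moves the spectrum along
# a component-specific direction.
.bandCenters <- c(6780, 5760, 5130, 4700, 4280)
.bandWidths  <- c(260, 150, 130, 120, 110)

.defaultBandTable <- function(amplitudes, baseline) {
    list(baseline = baseline,
         bands = data.frame(center = .bandCenters, width = .bandWidths,
                            amplitude = amplitudes))
}

.gaussianSpectrum <- function(grid, params) {
    s <- rep(params$baseline, length(grid))
    b <- params$bands
    for (i in seq_len(nrow(b)))
        s <- s + b$amplitude[i] *
            exp(-((grid - b$center[i])^2) / (2 * b$width[i]^2))
    s
}

#' Build the endmember component library
#'
#' Each raw material gets a strictly positive absorbance spectrum on the
#' shared grid, modelled as a baseline constant plus Gaussian bands at the
#' canonical NIR peak positions (6780, 5760, 5130, 4700, 4280 cm^-1);
#' troughs (6055, 5360, 4950, 4500, 4160 cm^-1) arise between bands.  Small
#' seeded perturbations of the band amplitudes differentiate components of
#' the same seed family.  Brand-specific analyte variants (requested via
#' `silkVariants`) differ from the shared analyte endmember in band
#' amplitudes only, emulating brand-to-brand differences in the analyte
#' material itself.
#'
#' @param grid strictly descending wavenumber grid (cm^-1).
#' @param seed integer RNG seed; the library is deterministic per seed.
#' @param silkVariants character vector of variant identifiers; each adds
#'   an endmember `"tobacco_silk@<id>"`.
#' @param amplitudeScale multiplier on all band amplitudes (0 collapses
#'   every endmember to its baseline constant).
#' @param variantSD log-normal SD of the band-amplitude perturbation that
#'   differentiates brand-specific analyte variants from the shared
#'   analyte endmember.
#' @return a [ComponentLibrary-class] with endmembers `tobacco_silk`,
#'   `cut_stem`, `fermented_cut_stem`, `expanded_tobacco_silk` plus any
#'   variants.
#' @export
makeComponentLibrary <- function(grid, seed = 1L, silkVariants = character(),
                                 amplitudeScale = 1, variantSD = 0.05) {
    if (!length(grid)) stop("empty wavenumber grid")
    if (length(grid) > 1L && !all(diff(grid) < 0))
        stop("grid must be strictly descending")
    base <- list(
        tobacco_silk          = c(0.30, 0.55, 0.48, 0.42, 0.35),
        cut_stem              = c(0.22, 0.38, 0.55, 0.30, 0.42),
        fermented_cut_stem    = c(0.24, 0.40, 0.52, 0.32, 0.40),
        expanded_tobacco_silk = c(0.34, 0.46, 0.40, 0.50, 0.28))
    baselines <- c(tobacco_silk = 0.35, cut_stem = 0.30,
                   fermented_cut_stem = 0.31, expanded_tobacco_silk = 0.33)
    withSeed(seed, {
        params <- list()
        for (nm in names(base)) {
            amp <- base[[nm]] * exp(rnorm(5, sd = 0.03)) * amplitudeScale
            params[[nm]] <- .defaultBandTable(amp, baselines[[nm]])
        }
        for (v in silkVariants) {
            # variant analyte: same bands, amplitudes multiplicatively
            # perturbed relative to the shared analyte
            amp <- params$tobacco_silk$bands$amplitude *
                exp(rnorm(5, sd = variantSD))
            params[[paste0("tobacco_silk@", v)]] <-
                .defaultBandTable(amp, baselines[["tobacco_silk"]])
        }
        endmembers <- lapply(params, .gaussianSpectrum, grid = grid)
        new("ComponentLibrary", wavenumbers = as.numeric(grid),
            endmembers = endmembers, bandParams = params)
    })
}

#' Draw blending compositions for one brand design
#'
#' Minor (non-analyte) components are drawn uniformly inside their boxes
#' and the analyte takes the remainder to 100%; draws whose remainder
#' leaves the analyte's box are rejected and redrawn, so every returned
#' composition honours the boxes exactly and sums to 100.
#'
#' @param design a [BrandDesign-class].
#' @param seed integer RNG seed.
#' @return numeric matrix, `nSamples` x components (named columns), rows
#'   summing to 100 within 1e-9.
#' @export
sampleBlendDesign <- function(design, seed = 1L) {
    validObject(design)
    rg <- design@componentRanges
    analyte <- design@analyte
    minors <- setdiff(names(rg), analyte)
    n <- design@nSamples
    lo <- vapply(rg[minors], `[`, numeric(1), 1L)
    hi <- vapply(rg[minors], `[`, numeric(1), 2L)
    aLo <- rg[[analyte]][1L]; aHi <- rg[[analyte]][2L]
    if (sum(lo) + aLo > 100 + 1e-9 || sum(hi) + aHi < 100 - 1e-9)
        stop("infeasible design: ranges cannot reach a 100% total")
    out <- matrix(0, n, length(rg),
                  dimnames = list(NULL, c(analyte, minors)))
    withSeed(seed, {
        for (i in seq_len(n)) {
            repeat {
                m <- lo + runif(length(minors)) * (hi - lo)
                a <- 100 - sum(m)
                if (a >= aLo - 1e-12 && a <= aHi + 1e-12) break
            }
            out[i, ] <- c(min(max(a, aLo), aHi), m)
        }
    })
    out
}

#' Synthesize a blended-spectra dataset for one brand
#'
#' Implements the linear (Beer-Lambert) mixing model with a brand-level
#' domain shift: for sample i with composition fractions f (percent),
#' `spectrum_i = gain * sum_c (f_ic/100) * endmember_c + offset +
#' slope * (w - mean(w)) + noise`, with i.i.d. Gaussian noise per grid
#' point.  The response is the analyte component's percentage.
#'
#' @param library a [ComponentLibrary-class].
#' @param design a [BrandDesign-class]; components with a brand-specific
#'   analyte variant use the endmember `"<analyte>@<silkVariant>"`.
#' @param shift a [DomainShift-class].
#' @param seed integer RNG seed driving the composition sampling.
#' @param noiseSeed integer RNG seed for the measurement noise; defaults to
#'   a child of `seed`.  Varying it alone changes the absorbance matrix but
#'   leaves the compositions (and hence the targets) untouched.
#' @return a [SpectralSet-class] with `design@nSamples` samples.
#' @export
synthesizeDataset <- function(library, design, shift = domainShift(),
                              seed = 1L, noiseSeed = childSeed(seed, 1L)) {
    validObject(library); validObject(design); validObject(shift)
    comp <- sampleBlendDesign(design, seed = seed)
    w <- library@wavenumbers
    resolve <- function(nm) {
        if (nm == design@analyte && nzchar(design@silkVariant))
            nm <- paste0(nm, "@", design@silkVariant)
        if (is.null(library@endmembers[[nm]]))
            stop("configuration error: component '", nm,
                 "' missing from the library")
        library@endmembers[[nm]]
    }
    E <- vapply(colnames(comp), resolve, numeric(length(w)))
    clean <- (comp / 100) %*% t(E)                     # n x d
    tilt <- shift@offset + shift@slope * (w - mean(w)) # length d
    X <- shift@gain * clean + matrix(tilt, nrow(comp), length(w),
                                     byrow = TRUE)
    if (shift@noiseSD > 0)
        X <- X + withSeed(noiseSeed,
                          matrix(rnorm(length(X), sd = shift@noiseSD),
                                 nrow(X), ncol(X)))
    SpectralSet(X, w, target = comp[, design@analyte],
                brand = design@brand,
                sampleID = sprintf("%s_%03d", design@brand,
                                   seq_len(nrow(comp))))
}

#' The default four-brand blending designs
#'
#' Brand 1 blends the analyte (59-100%) with cut stem (0-20%), fermented
#' cut stem (0-20%) and expanded material (0-25%); brands 2-4 blend the
#' analyte (75-100%) with a single minor component (0-25%): fermented cut
#' stem for brand 2, cut stem for brands 3 and 4.  Sample counts are
#' 210/199/200/183.  Brands 1 and 4 use brand-specific analyte variants.
#'
#' @return named list of four [BrandDesign-class] objects (`B1`-`B4`).
#' @export
defaultBrandDesigns <- function() {
    list(
        B1 = brandDesign("B1", 210L,
                         list(tobacco_silk = c(59, 100),
                              cut_stem = c(0, 20),
                              fermented_cut_stem = c(0, 20),
                              expanded_tobacco_silk = c(0, 25)),
                         silkVariant = "B1"),
        B2 = brandDesign("B2", 199L,
                         list(tobacco_silk = c(75, 100),
                              fermented_cut_stem = c(0, 25))),
        B3 = brandDesign("B3", 200L,
                         list(tobacco_silk = c(75, 100),
                              cut_stem = c(0, 25))),
        B4 = brandDesign("B4", 183L,
                         list(tobacco_silk = c(75, 100),
                              cut_stem = c(0, 25)),
                         silkVariant = "B4"))
}

#' The default brand-level domain shifts
#'
#' Brands 2 and 3 differ only by small additive offsets (near-identical
#' domains); brands 1 and 4 are strongly shifted in opposite directions
#' (large offset and baseline tilt, mild gain) and additionally use their
#' own analyte endmember variants, reproducing the similar-vs-divergent
#' brand structure the transfer study probes.
#'
#' @param noiseSD measurement noise SD shared by all brands (absorbance
#'   units); the default corresponds to averaging duplicate scans of a
#'   typical FT-NIR acquisition.
#' @return named list of four [DomainShift-class] objects.
#' @export
defaultBrandShifts <- function(noiseSD = 0.015) {
    list(
        B1 = domainShift(offset =  0.015, slope =  5e-6, gain = 1.02,
                         noiseSD = noiseSD),
        B2 = domainShift(offset =  0.0005, slope = 0, gain = 1,
                         noiseSD = noiseSD),
        B3 = domainShift(offset = -0.0005, slope = 0, gain = 1,
                         noiseSD = noiseSD),
        B4 = domainShift(offset = -0.015, slope = -5e-6, gain = 0.98,
                         noiseSD = noiseSD))
}

#' Generate the default four-brand study
#'
#' Builds the component library (with brand-specific analyte variants for
#' brands 1 and 4), draws each brand's blending design and synthesizes one
#' dataset per brand under its domain shift.  Deterministic per seed.
#'
#' @param seed integer master seed.
#' @param grid wavenumber grid; defaults to 10,000-4,000 cm^-1 at 4 cm^-1.
#' @param shifts named list of [DomainShift-class] per brand; defaults to
#'   [defaultBrandShifts()].
#' @param designs named list of [BrandDesign-class]; defaults to
#'   [defaultBrandDesigns()].
#' @param variantSD band-amplitude perturbation of brand-specific analyte
#'   variants (see [makeComponentLibrary()]).
#' @return named list of four [SpectralSet-class] datasets.
#' @examples
#' study <- defaultFourBrandStudy(1, grid = defaultGrid(10000, 4000, 100))
#' vapply(study, ncol, integer(1))  # 210 199 200 183
#' @export
defaultFourBrandStudy <- function(seed = 1L, grid = defaultGrid(),
                                  shifts = defaultBrandShifts(),
                                  designs = defaultBrandDesigns(),
                                  variantSD = 0.05) {
    variants <- unique(vapply(designs, slot, character(1), "silkVariant"))
    variants <- variants[nzchar(variants)]
    lib <- makeComponentLibrary(grid, seed = childSeed(seed, 0L),
                                silkVariants = variants,
                                variantSD = variantSD)
    out <- list()
    for (i in seq_along(designs)) {
        nm <- names(designs)[i]
        sh <- if (nm %in% names(shifts)) shifts[[nm]] else domainShift()
        out[[nm]] <- synthesizeDataset(lib, designs[[i]], sh,
                                       seed = childSeed(seed, i))
    }
    out
}
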