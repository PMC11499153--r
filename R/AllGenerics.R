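## Generics, accessors and show methods.

#' Accessors for diffusion-parameter containers
#'
#' Extract the physical parameters from a
#' \code{\linkS4class{DiffusionParams}} or from the fitted parameters of a
#' \code{\linkS4class{FitResult}}.
#'
#' @param object a \code{DiffusionParams} or \code{FitResult}.
#' @return a single numeric value.
#' @examples
#' p <- DiffusionParams(0.19, 1.6, 5e-3)
#' volumeFraction(p); tortuosity(p); uptakeRate(p)
#' @name diffusion-accessors
NULL

#' @rdname diffusion-accessors
#' @export
setGeneric("volumeFraction", function(object) standardGeneric("volumeFraction"))
#' @rdname diffusion-accessors
#' @export
setGeneric("tortuosity", function(object) standardGeneric("tortuosity"))
#' @rdname diffusion-accessors
#' @export
setGeneric("uptakeRate", function(object) standardGeneric("uptakeRate"))
#' @rdname diffusion-accessors
#' @export
setGeneric("freeDiffusion", function(object) standardGeneric("freeDiffusion"))
#' @rdname diffusion-accessors
#' @export
setGeneric("transportNumber",
           function(object) standardGeneric("transportNumber"))

#' @rdname diffusion-accessors
setMethod("volumeFraction", "DiffusionParams", function(object) object@alpha)
#' @rdname diffusion-accessors
setMethod("tortuosity", "DiffusionParams", function(object) object@lam)
#' @rdname diffusion-accessors
setMethod("uptakeRate", "DiffusionParams", function(object) object@kprime)
#' @rdname diffusion-accessors
setMethod("freeDiffusion", "DiffusionParams", function(object) object@D)
#' @rdname diffusion-accessors
setMethod("transportNumber", "DiffusionParams",
          function(object) object@n_transport)

#' Accessors for fit results
#'
#' @param object a \code{\linkS4class{FitResult}}.
#' @return \code{fitParams}: the fitted
#'   \code{\linkS4class{DiffusionParams}}; \code{fitSSE}: the residual sum
#'   of squares in (mM)^2; \code{isConverged}: logical.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname fit-accessors
#' @export
setGeneric("fitSSE", function(object) standardGeneric("fitSSE"))
#' @rdname fit-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname fit-accessors
setMethod("fitParams", "FitResult", function(object) object@params)
#' @rdname fit-accessors
setMethod("fitSSE", "FitResult", function(object) object@sse)
#' @rdname fit-accessors
setMethod("isConverged", "FitResult", function(object) object@converged)

#' @rdname diffusion-accessors
setMethod("volumeFraction", "FitResult",
          function(object) object@params@alpha)
#' @rdname diffusion-accessors
setMethod("tortuosity", "FitResult", function(object) object@params@lam)
#' @rdname diffusion-accessors
setMethod("uptakeRate", "FitResult", function(object) object@params@kprime)
#' @rdname diffusion-accessors
setMethod("freeDiffusion", "FitResult", function(object) object@params@D)
#' @rdname diffusion-accessors
setMethod("transportNumber", "FitResult",
          function(object) object@params@n_transport)

#' Accessors for curves and time series
#'
#' @param object a \code{\linkS4class{DiffusionCurve}},
#'   \code{\linkS4class{ImageTimeSeries}} or
#'   \code{\linkS4class{VolumeTimecourse}}.
#' @return numeric vectors (times in s for curves, min for image series;
#'   concentration in mM; soma area in um^2; volume in percent).
#' @name series-accessors
NULL

#' @rdname series-accessors
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))
#' @rdname series-accessors
#' @export
setGeneric("curveConc", function(object) standardGeneric("curveConc"))
#' @rdname series-accessors
#' @export
setGeneric("curveBaseline", function(object) standardGeneric("curveBaseline"))
#' @rdname series-accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname series-accessors
#' @export
setGeneric("volPercent", function(object) standardGeneric("volPercent"))
#' @rdname series-accessors
#' @export
setGeneric("somaArea", function(object) standardGeneric("somaArea"))
#' @rdname series-accessors
#' @export
setGeneric("roiFI", function(object) standardGeneric("roiFI"))
#' @rdname series-accessors
#' @export
setGeneric("nBaseline", function(object) standardGeneric("nBaseline"))

#' @rdname series-accessors
setMethod("curveTimes", "DiffusionCurve", function(object) object@t)
#' @rdname series-accessors
setMethod("curveConc", "DiffusionCurve", function(object) object@conc_mM)
#' @rdname series-accessors
setMethod("curveBaseline", "DiffusionCurve",
          function(object) object@baseline_mM)
#' @rdname series-accessors
setMethod("timePoints", "ImageTimeSeries", function(object) object@timepoints)
#' @rdname series-accessors
setMethod("timePoints", "VolumeTimecourse", function(object) object@t)
#' @rdname series-accessors
setMethod("volPercent", "VolumeTimecourse", function(object) object@vol_pct)
#' @rdname series-accessors
setMethod("somaArea", "VolumeTimecourse", function(object) object@ss)
#' @rdname series-accessors
setMethod("roiFI", "VolumeTimecourse", function(object) object@fi)
#' @rdname series-accessors
setMethod("nBaseline", "ImageTimeSeries",
          function(object) object@n_baseline)

setMethod("show", "DiffusionParams", function(object) {
  cat("DiffusionParams:\n")
  cat(sprintf("  alpha = %.4g, lambda = %.4g, k' = %.4g 1/s\n",
              object@alpha, object@lam, object@kprime))
  cat(sprintf("  D = %.4g cm^2/s, transport number n = %.4g\n",
              object@D, object@n_transport))
})

setMethod("show", "SourceConfig", function(object) {
  cat("SourceConfig:\n")
  cat(sprintf("  step %.4g nA on bias %.4g nA, duration %.4g s\n",
              object@i_step * 1e9, object@i_bias * 1e9, object@duration_s))
  cat(sprintf("  separation r = %.4g um, baseline %.4g mM TMA+\n",
              cmToUm(object@r), molPerCm3ToMM(object@c_baseline)))
})

setMethod("show", "DiffusionCurve", function(object) {
  cat(sprintf("DiffusionCurve (%s): %d samples, t in [%.4g, %.4g] s\n",
              object@medium, length(object@t),
              min(object@t), max(object@t)))
  cat(sprintf("  baseline %.4g mM, pulse onset at %.4g s (%.4g s step)\n",
              object@baseline_mM, object@onset_s, object@source@duration_s))
})

setMethod("show", "IsmCalibration", function(object) {
  cat(sprintf(
    "IsmCalibration: v0 = %.4g mV, slope = %.4g mV/decade, interference = %.4g mM",
    object@v0, object@slope, object@interference))
  if (is.finite(object@rms_mV))
    cat(sprintf(" (fit RMS %.3g mV)", object@rms_mV))
  cat("\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s): SSE = %.4g (mM)^2, %d evaluations\n",
              if (object@converged) "converged" else "NOT converged",
              object@sse, as.integer(object@n_iter)))
  show(object@params)
  bf <- object@diagnostics$bound_flags
  if (!is.null(bf) && any(bf))
    cat("  bound-constrained:", paste(names(bf)[bf], collapse = ", "), "\n")
})

setMethod("show", "ImageTimeSeries", function(object) {
  d <- dim(object@stacks[[1]])
  cat(sprintf(
    "ImageTimeSeries: %d stacks of %d x %d x %d voxels (%.3g x %.3g x %.3g um)\n",
    length(object@stacks), d[1], d[2], d[3],
    object@voxel_size[1], object@voxel_size[2], object@voxel_size[3]))
  cat(sprintf("  timepoints (min): %s; %d baseline stacks\n",
              paste(signif(object@timepoints, 3), collapse = ", "),
              object@n_baseline))
})

setMethod("show", "VolumeTimecourse", function(object) {
  cat(sprintf("VolumeTimecourse: %d timepoints, reference #%d\n",
              length(object@t), object@reference_index))
  cat(sprintf("  vol%%: %s\n",
              paste(signif(object@vol_pct, 4), collapse = ", ")))
})
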