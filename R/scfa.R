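#' @include AllClasses.R
NULL

#' Default external standard concentrations (mM)
#'
#' The 8-point series spanning the working range of the SCFA assay.
#' @export
scfaStandardSeries <- function() c(0.1, 0.2, 0.5, 1, 2, 4, 8, 16)

.checkProfiles <- function(profiles) {
  needed <- c("donor", "treatment", "replicate", "acid", "concentration_mM")
  if (!is.data.frame(profiles) || !all(needed %in% names(profiles)))
    stop("SCFA profile table needs columns: ", paste(needed, collapse = ", "))
  bad <- setdiff(unique(profiles$acid), SCFA_ACIDS)
  if (length(bad))
    stop("unknown acid name(s): ", paste(bad, collapse = ", "),
         " (expected C2:C5 vocabulary: ", paste(SCFA_ACIDS, collapse = ", "),
         ")")
  if (any(!is.finite(profiles$concentration_mM)) ||
      any(profiles$concentration_mM < 0))
    stop("concentrations must be finite and >= 0")
  invisible(profiles)
}

#' Fit an SCFA calibration curve
#'
#' Ordinary least-squares fit of detector response against standard
#' concentration, `response = slope * concentration + intercept`, as used for
#' external-standard quantification on a GC-FID.  The default standard series
#' is an 8-point curve at 0.1, 0.2, 0.5, 1, 2, 4, 8 and 16 mM.
#'
#' @param concentration standard concentrations in mM (>= 2 distinct values).
#' @param response detector responses at those concentrations.
#' @param acid optional acid name recorded on the curve.
#' @return a [CalibrationCurve-class].
#' @examples
#' fitStandardCurve(scfaStandardSeries(), 5 * scfaStandardSeries() + 1)
#' @export
fitStandardCurve <- function(concentration, response, acid = "") {
  if (length(concentration) != length(response))
    stop("concentration and response must have equal length")
  if (length(concentration) < 2L || length(unique(concentration)) < 2L)
    stop("need at least two distinct standard concentrations")
  fit <- lm(response ~ concentration)
  # summary.lm warns on an exact fit; r^2 itself is well-defined there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # exact fit with zero residual and zero total SS
  new("CalibrationCurve",
      acid = as.character(acid),
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      rSquared = r2,
      standardConcentrations = as.numeric(concentration))
}

#' Back-calculate SCFA concentrations from detector responses
#'
#' Inverts the calibration line per acid: `conc = (response - intercept) /
#' slope`.  Responses below the intercept give negative back-calculated
#' concentrations, which are floored to 0 mM with a warning (concentrations
#' are physically non-negative).
#'
#' @param responses named numeric vector of detector responses (names are
#'   acid names).
#' @param curves named list of [CalibrationCurve-class] objects covering
#'   every acid in `responses`.
#' @return named numeric vector of concentrations in mM.
#' @export
quantifyScfa <- function(responses, curves) {
  if (is.null(names(responses)) || !all(nzchar(names(responses))))
    stop("responses must be a named vector (acid names)")
  missing <- setdiff(names(responses), names(curves))
  if (length(missing))
    stop("no calibration curve for acid(s): ", paste(missing, collapse = ", "))
  conc <- vapply(names(responses), function(a) {
    cv <- curves[[a]]
    (responses[[a]] - cv@intercept) / cv@slope
  }, numeric(1L))
  # tolerance so a blank sitting exactly on the intercept is not flagged
  meaningfullyNegative <- conc < -1e-8 * pmax(1, abs(responses))
  if (any(meaningfullyNegative))
    warning("response(s) below calibration intercept for ",
            paste(names(conc)[meaningfullyNegative], collapse = ", "),
            "; concentration floored to 0 mM")
  conc[conc < 0] <- 0
  conc
}

#' Total SCFA per fermentation vessel
#'
#' Sums the C2:C5 acid concentrations within each donor x treatment x
#' replicate vessel.
#'
#' @param profiles long-format SCFA table with columns `donor`, `treatment`,
#'   `replicate`, `acid`, `concentration_mM`.
#' @return data.frame with columns `donor`, `treatment`, `replicate`,
#'   `total_mM`.
#' @export
totalScfa <- function(profiles) {
  .checkProfiles(profiles)
  agg <- aggregate(concentration_mM ~ donor + treatment + replicate,
                   data = profiles, FUN = sum)
  names(agg)[names(agg) == "concentration_mM"] <- "total_mM"
  agg[order(agg$donor, agg$treatment, agg$replicate), , drop = FALSE]
}

#' Control-corrected SCFA fold changes
#'
#' Divides each treatment vessel's total SCFA by the total of the matched
#' unsupplemented control vessel of the same donor, correcting for
#' between-donor differences in cell viability and residual stool nutrients.
#' Pairing is within donor and replicate index; when a donor's control
#' replicate count differs from the treatment's, the mean control total of
#' that donor is used as the denominator instead.  Donors whose control total
#' is zero are dropped with a warning (the ratio is undefined).
#'
#' @inheritParams totalScfa
#' @param control name of the unsupplemented treatment (default
#'   `"control"`).
#' @return data.frame with columns `donor`, `prebiotic`, `replicate`,
#'   `fold_change` (treatment total / control total, unitless, > 0); the
#'   control itself does not appear.
#' @export
foldChange <- function(profiles, control = "control") {
  totals <- totalScfa(profiles)
  if (!control %in% totals$treatment)
    stop("no '", control, "' vessels found")
  ctl <- totals[totals$treatment == control, , drop = FALSE]
  trt <- totals[totals$treatment != control, , drop = FALSE]
  missing <- setdiff(unique(trt$donor), unique(ctl$donor))
  if (length(missing))
    stop("missing control vessel(s) for donor(s): ",
         paste(missing, collapse = ", "))
  zeroDonors <- unique(ctl$donor[ctl$total_mM == 0])
  if (length(zeroDonors)) {
    warning("control total SCFA is 0 mM for donor(s) ",
            paste(zeroDonors, collapse = ", "),
            "; fold change undefined, rows dropped")
    ctl <- ctl[!ctl$donor %in% zeroDonors, , drop = FALSE]
    trt <- trt[!trt$donor %in% zeroDonors, , drop = FALSE]
  }
  rows <- lapply(split(trt, trt$donor), function(td) {
    cd <- ctl[ctl$donor == td$donor[1L], , drop = FALSE]
    paired <- setdiff(unique(td$replicate), unique(cd$replicate))
    denom <- if (length(paired) == 0L &&
                 length(unique(cd$replicate)) >=
                   length(unique(td$replicate))) {
      cd$total_mM[match(td$replicate, cd$replicate)]
    } else {
      rep(mean(cd$total_mM), nrow(td))
    }
    data.frame(donor = td$donor, prebiotic = td$treatment,
               replicate = td$replicate,
               fold_change = td$total_mM / denom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(donor = character(), prebiotic = character(),
                      replicate = integer(), fold_change = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$donor, out$prebiotic, out$replicate), , drop = FALSE]
}

#' Daily fiber dose equivalent of the in vitro prebiotic:stool ratio
#'
#' Converts the in vitro mixing ratio (percent w/v prebiotic over percent
#' w/v fecal slurry) into the daily fiber intake whose ratio to daily stool
#' mass matches it: `stool_g_per_day * prebiotic_pct / slurry_pct`.  With a
#' 5% slurry, 0.5% prebiotic and 200 g/day stool this is 20 g/day of dietary
#' fiber.
#'
#' @param stoolGPerDay assumed daily stool mass in grams (> 0).
#' @param slurryPctWV fecal slurry concentration, percent w/v (> 0).
#' @param prebioticPctWV prebiotic concentration, percent w/v (> 0).
#' @return equivalent fiber intake in grams/day.
#' @examples
#' fiberDoseEquivalent(200, 5, 0.5)  # 20
#' @export
fiberDoseEquivalent <- function(stoolGPerDay = 200, slurryPctWV = 5,
                                prebioticPctWV = 0.5) {
  args <- c(stoolGPerDay, slurryPctWV, prebioticPctWV)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("all arguments must be positive")
  stoolGPerDay * prebioticPctWV / slurryPctWV
}
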