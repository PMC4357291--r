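#' Copy-number calibration from patch intensity samples
#'
#' The average number of molecules of the target protein at a patch is
#' estimated as \eqn{n_p = c\,(f/g)\,n_r}, where `f` and `g` are the median
#' per-spot fluorescence intensities of the target and reference protein
#' (imaged together, same tag), `n_r` is the known copy number of the
#' reference and `c` an optional tag-brightness correction (1 when target
#' and reference carry the same fluorophore variant).
#'
#' Target intensity distributions are skewed, so their spread is measured
#' after a logarithmic transformation:
#' \eqn{\delta_l = 1.4826 \times \mathrm{MAD}(\log f_i)/\sqrt{N}}; the
#' reference spread \eqn{\delta_g} is the analogous MAD-based standard
#' error on the raw reference intensities. With `c = 1` the propagated
#' uncertainty is
#' \deqn{\delta n_p = \sqrt{(n_r \tfrac{f}{g}\delta_l)^2 +
#'   (n_r \tfrac{f}{g^2}\delta_g)^2 + (\tfrac{f}{g}\delta n_r)^2};}
#' with a tag correction the four-term extension adds
#' \eqn{(\tfrac{f}{g} n_r \delta_c)^2} and carries `c` through the first
#' three terms.
#'
#' @param target_intensities per-spot background-corrected intensities of
#'   the target protein (> 0; the log transform requires positivity).
#' @param ref_intensities per-spot intensities of the reference protein.
#' @param n_r reference copy number (molecules per spot).
#' @param dn_r standard error of `n_r`.
#' @param c_tag tag-brightness correction factor (default 1).
#' @param dc_tag standard error of `c_tag` (default 0).
#' @return A list of class `molecule_calibration` with `n_p`, `dn_p`, the
#'   medians `f`, `g`, the spreads `delta_l`, `delta_g`, and the inputs.
#' @export
copy_number <- function(target_intensities, ref_intensities, n_r, dn_r,
                        c_tag = 1, dc_tag = 0) {
  Nf <- length(target_intensities)
  Ng <- length(ref_intensities)
  if (Nf < 3L || Ng < 3L)
    stop("at least 3 intensity samples per channel are required")
  if (any(target_intensities <= 0))
    stop("non-positive target intensity: the log transform requires ",
         "positive values")
  if (any(ref_intensities <= 0))
    stop("non-positive reference intensity")
  f <- stats::median(target_intensities)
  g <- stats::median(ref_intensities)
  delta_l <- 1.4826 * stats::mad(log(target_intensities), constant = 1) /
    sqrt(Nf)
  delta_g <- 1.4826 * stats::mad(ref_intensities, constant = 1) / sqrt(Ng)
  n_p <- c_tag * (f / g) * n_r
  # delta_l lives on the log scale: n_r f/g delta_l is a relative error
  # times the estimate
  dn_p <- sqrt((c_tag * n_r * (f / g) * delta_l)^2 +
               (c_tag * n_r * (f / g^2) * delta_g)^2 +
               (c_tag * (f / g) * dn_r)^2 +
               ((f / g) * n_r * dc_tag)^2)
  structure(list(n_p = n_p, dn_p = dn_p, f = f, g = g,
                 delta_l = delta_l, delta_g = delta_g,
                 n_r = n_r, dn_r = dn_r, c_tag = c_tag, dc_tag = dc_tag,
                 N_target = Nf, N_ref = Ng),
            class = "molecule_calibration")
}

#' @export
print.molecule_calibration <- function(x, ...) {
  cat(sprintf("copy number: %.1f +/- %.1f molecules (f/g = %.3f, n_r = %.1f)\n",
              x$n_p, x$dn_p, x$f / x$g, x$n_r))
  invisible(x)
}

#' Calibrate a fluorescence intensity curve into molecule numbers
#'
#' The fluorescence curve of an average trajectory is rescaled so that its
#' baseline-subtracted time average equals the calibrated copy number:
#' \deqn{P^n_i = n_p\,\frac{P^f_i - P^f_{min}}{\bar F},\qquad
#'   \bar F = \frac{1}{N}\sum_j (P^f_j - P^f_{min}),}
#' with \eqn{P^f_{min} = \min_k P^f_k}. Uncertainties combine the copy
#' number error, the per-point fluorescence error (including its effect on
#' \eqn{\bar F}), and the error \eqn{\delta_m} of the fluorescence value at
#' the minimum index:
#' \deqn{\delta^n_i = \Big[\big(\tfrac{P^f_i - P^f_{min}}{\bar F}\,
#'   \delta n_p\big)^2 + \big(n_p\,\tfrac{N\bar F - P^f_i + P^f_{min}}
#'   {N \bar F^2}\,\delta^f_i\big)^2 + \big(n_p\,\tfrac{P^f_i - P^f_{min}
#'   - \bar F}{\bar F^2}\,\delta_m\big)^2\Big]^{1/2}.}
#'
#' @param P an `avg_trajectory` with fluorescence column `f` and standard
#'   errors `df`.
#' @param cal a `molecule_calibration` from [copy_number()].
#' @return A data frame of class `molecule_curve` with columns `i`, `t`,
#'   `n` (molecules), `dn` (standard error); attributes `f_min`, `F_bar`,
#'   `n_p`.
#' @export
calibrate_curve <- function(P, cal) {
  f <- P$f
  df <- P$df
  df[is.na(df)] <- 0
  N <- length(f)
  l <- which.min(f)
  f_min <- f[l]
  F_bar <- mean(f - f_min)
  if (F_bar <= 0)
    stop("fluorescence curve is constant: rescaling is undefined")
  n_p <- cal$n_p
  n_curve <- n_p * (f - f_min) / F_bar
  delta_m <- df[l]
  dn <- sqrt(((f - f_min) / F_bar * cal$dn_p)^2 +
             (n_p * (N * F_bar - f + f_min) / (N * F_bar^2) * df)^2 +
             (n_p * (f - f_min - F_bar) / F_bar^2 * delta_m)^2)
  structure(data.frame(i = P$i, t = P$t, n = n_curve, dn = dn),
            f_min = f_min, F_bar = F_bar, n_p = n_p, min_index = l,
            class = c("molecule_curve", "data.frame"))
}

#' Tagged fraction from replicate band ratios
#'
#' The fraction of tagged protein when a tagged copy is co-expressed with
#' the untagged endogenous protein. `r` is the mean tagged/untagged band
#' ratio over replicate quantifications, and the tagged fraction is
#' \eqn{\tilde r = r/(r+1)} with standard error
#' \eqn{\sigma_{\tilde r} = \sigma_r/(r+1)^2}.
#'
#' @param replicate_ratios tagged/untagged ratios, one per replicate
#'   (>= 2, non-negative).
#' @return A list of class `tagged_fraction` with `r`, `sr` (SE of the
#'   mean), `r_tilde`, `sr_tilde`.
#' @export
tagged_fraction <- function(replicate_ratios) {
  if (length(replicate_ratios) < 2L) stop("at least 2 replicates required")
  if (any(replicate_ratios < 0)) stop("ratios must be non-negative")
  r <- mean(replicate_ratios)
  sr <- stats::sd(replicate_ratios) / sqrt(length(replicate_ratios))
  structure(list(r = r, sr = sr,
                 r_tilde = r / (r + 1), sr_tilde = sr / (r + 1)^2),
            class = "tagged_fraction")
}

#' Average filament length from monomer and filament counts
#'
#' If each nucleator complex seeds one filament, the mean filament length
#' follows from the monomer count, the filament count and the axial rise
#' per subunit of the actin helix.
#'
#' @param n_monomers total polymerised monomers.
#' @param n_filaments number of filaments.
#' @param rise_nm axial rise per subunit (nm; 2.7 for actin).
#' @return A list with `subunits_per_filament` and `mean_length_nm`.
#' @export
filament_length_estimate <- function(n_monomers, n_filaments,
                                     rise_nm = 2.7) {
  stopifnot(n_monomers > 0, n_filaments > 0, rise_nm > 0)
  subunits <- n_monomers / n_filaments
  list(subunits_per_filament = subunits,
       mean_length_nm = subunits * rise_nm)
}
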