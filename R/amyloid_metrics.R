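#' Amyloid-load / Centiloid conversion constants
#'
#' The amyloid-load metric (abbreviated `abl` throughout) is linearly related
#' to the Centiloid (CL) scale; the early amyloid-positivity (A+) cutoff is
#' 13.3 amyloid-load units, approximately 18.0 CL. The slope/intercept are
#' used at their published two- and three-digit precision, so the cutoff maps
#' to 18.091 CL rather than exactly 18.0; the 0.09 CL discrepancy is accepted.
#'
#' @return A list with elements `slope` (CL per amyloid-load unit),
#'   `intercept` (CL), `cutoff_abl` and `cutoff_cl`.
#' @export
#' @examples
#' cl_constants()$cutoff_abl
cl_constants <- function() {
  list(slope = 2.27, intercept = -12.1, cutoff_abl = 13.3, cutoff_cl = 18.0)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

#' Convert amyloid load to Centiloids
#'
#' Applies the linear calibration `CL = 2.27 * abl - 12.1`. Vectorized.
#'
#' @param abl Amyloid-load value(s).
#' @return Centiloid value(s), same length as `abl`.
#' @seealso [cl_to_abl()] for the inverse map.
#' @export
#' @examples
#' abl_to_cl(13.3) # the A+ cutoff, ~18 CL
abl_to_cl <- function(abl) {
  check_finite(abl, "abl")
  k <- cl_constants()
  k$slope * abl + k$intercept
}

#' Convert Centiloids to amyloid load
#'
#' Inverse of [abl_to_cl()]: `abl = (cl + 12.1) / 2.27`.
#'
#' @param cl Centiloid value(s).
#' @return Amyloid-load value(s).
#' @export
cl_to_abl <- function(cl) {
  check_finite(cl, "cl")
  k <- cl_constants()
  (cl - k$intercept) / k$slope
}

#' Classify amyloid positivity
#'
#' A scan is A+ when its amyloid load is at or above the cutoff (13.3 by
#' default). The boundary is inclusive: a chronicity of 0 years corresponds to
#' the cutoff itself, which therefore sits on the positive side.
#'
#' @param abl Amyloid-load value(s).
#' @param cutoff Positivity cutoff in amyloid-load units.
#' @return Logical vector.
#' @export
#' @examples
#' is_apositive(c(13.29, 13.3))
is_apositive <- function(abl, cutoff = cl_constants()$cutoff_abl) {
  check_finite(abl, "abl")
  abl >= cutoff
}

#' Voxelwise amyloid-load estimation by two-template least squares
#'
#' Decomposes a masked SUVR image (flattened to a voxel vector) into a
#' specific-binding component (a template of amyloid carrying capacity) and a
#' nonspecific-binding component, by unconstrained ordinary least squares:
#' `suvr ~ abl * template_k + ns_coeff * template_ns` over masked voxels. The
#' coefficient on the carrying-capacity template is the global amyloid load.
#'
#' No non-negativity constraint is imposed; a negative fitted amyloid load is
#' returned as-is with a warning, since near-zero-burden images can fit
#' slightly below zero.
#'
#' @param suvr Numeric voxel vector of SUVR values.
#' @param template_k Numeric voxel vector: amyloid carrying capacity template.
#' @param template_ns Numeric voxel vector: nonspecific binding template.
#' @param mask Logical voxel vector selecting the amyloid-carrying voxels that
#'   enter the fit; `NULL` uses all voxels.
#' @return A list with `abl` (amyloid load) and `ns_coeff` (nonspecific
#'   binding coefficient).
#' @export
#' @examples
#' k <- c(1, 2, 3, 4); ns <- c(1, 1, 2, 2)
#' estimate_abl_voxelwise(0.5 * k + 1.0 * ns, k, ns)
estimate_abl_voxelwise <- function(suvr, template_k, template_ns, mask = NULL) {
  n <- length(suvr)
  if (length(template_k) != n || length(template_ns) != n) {
    stop("`suvr`, `template_k` and `template_ns` must have equal length",
         call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n || !is.logical(mask)) {
    stop("`mask` must be a logical vector matching the voxel vectors",
         call. = FALSE)
  }
  if (sum(mask) < 2L) stop("mask must select at least 2 voxels", call. = FALSE)
  X <- cbind(k = template_k[mask], ns = template_ns[mask])
  qrX <- qr(X)
  if (qrX$rank < 2L) {
    stop("templates are collinear within the mask; fit is singular",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, suvr[mask])
  if (beta[["k"]] < 0) {
    warning("fitted amyloid load is negative; reporting as-is", call. = FALSE)
  }
  list(abl = unname(beta[["k"]]), ns_coeff = unname(beta[["ns"]]))
}

#' Read or write a voxel fixture table
#'
#' Voxel fixtures are flat CSV tables with columns `voxel_id`, `suvr`,
#' `template_k`, `template_ns`, `mask` (0/1) -- a minimal text stand-in for a
#' masked SUVR volume plus its two decomposition templates.
#'
#' @param path CSV file path.
#' @return `read_voxel_fixture()` returns a data.frame with a logical `mask`.
#' @export
read_voxel_fixture <- function(path) {
  df <- utils::read.csv(path)
  need <- c("voxel_id", "suvr", "template_k", "template_ns", "mask")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("voxel fixture is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$mask <- as.logical(df$mask)
  df
}

#' @rdname read_voxel_fixture
#' @param fixture Data frame in the voxel-fixture layout.
#' @export
write_voxel_fixture <- function(fixture, path) {
  fixture$mask <- as.integer(fixture$mask)
  utils::write.csv(fixture, path, row.names = FALSE)
  invisible(path)
}
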