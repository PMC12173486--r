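#' Gait-cycle loading profile
#'
#' A per-increment total triceps-surae force applied to the whole
#' Achilles tendon, indexed by one-percent increments of the gait cycle.
#'
#' @param total_force numeric vector of non-negative forces (N), one per
#'   gait-cycle increment.
#' @return a `gait_profile` object.
#' @seealso [synth_gait_profile()] for the synthetic default.
#' @export
gait_profile <- function(total_force) {
  if (length(total_force) < 1 || any(!is.finite(total_force)))
    stop("'total_force' must be a non-empty finite vector")
  if (any(total_force < 0)) stop("forces must be >= 0")
  structure(list(total_force = as.numeric(total_force),
                 n_increments = length(total_force)),
            class = "gait_profile")
}

#' Partition a total tendon force into per-subtendon axial stresses
#'
#' The two gastrocnemius subtendons are loaded identically
#' (`sigma_LG = sigma_MG = sigma_G`) and the soleus stress is a
#' prescribed multiple of the gastrocnemius stress
#' (`sigma_S = ratio * sigma_G`), with the total tendon force conserved:
#' `sigma_G = F / (A_LG + A_MG + ratio * A_S)`.  Stresses are determined
#' a priori on the undeformed distal cross-sectional areas.  The three
#' cohorts correspond to `ratio` 1 (uniform), 2 (soleus doubled) and 0.5
#' (soleus halved).
#'
#' @param total_force total Achilles tendon force, N (>= 0).
#' @param areas named per-subtendon areas (LG, MG, S), mm^2.
#' @param ratio soleus-to-gastrocnemius stress ratio (> 0).
#' @param twist_deg,increment optional identifiers carried on the result.
#' @return a `load_case`: list with `stress` (Pa, named LG/MG/S),
#'   `force` (N), `areas` (mm^2), `ratio`, `total_force`, `twist_deg`,
#'   `increment`.
#' @examples
#' lc <- partition_cohort_forces(1000, c(LG = 20, MG = 25, S = 55), ratio = 2)
#' lc$stress / 1e6   # MPa; soleus exactly twice the gastrocnemius
#' sum(lc$force)     # 1000 N conserved
#' @export
partition_cohort_forces <- function(total_force, areas, ratio = 1,
                                    twist_deg = NA_real_,
                                    increment = NA_integer_) {
  labs <- c("LG", "MG", "S")
  if (!all(labs %in% names(areas)))
    stop("'areas' must be named with LG, MG, S")
  areas <- areas[labs]
  if (any(areas <= 0) || sum(areas) <= 0)
    stop("subtendon areas must be positive")
  if (total_force < 0) stop("'total_force' must be >= 0")
  if (!is.finite(ratio) || ratio <= 0) stop("'ratio' must be > 0")
  a_m2 <- areas * 1e-6                       # mm^2 -> m^2
  sigma_g <- total_force / (a_m2[["LG"]] + a_m2[["MG"]] + ratio * a_m2[["S"]])
  stress <- c(LG = sigma_g, MG = sigma_g, S = ratio * sigma_g)
  structure(list(stress = stress, force = stress * a_m2,
                 areas = areas, ratio = ratio, total_force = total_force,
                 twist_deg = twist_deg, increment = increment),
            class = "load_case")
}

#' Build the full cohort x twist x gait-increment model batch
#'
#' One model specification per (cohort, twist, increment), in
#' deterministic order (cohort outermost, then twist, then increment).
#' The default grid -- 19 twist conditions (0 to 180 degrees in 10 degree
#' steps) and 100 gait increments -- yields 1900 specifications per
#' cohort.
#'
#' @param cohorts named numeric vector of soleus/gastrocnemius stress
#'   ratios; default `c(uniform = 1, soleus_doubled = 2, soleus_halved = 0.5)`.
#' @param twist_grid twist angles in degrees.
#' @param profile a [gait_profile()].
#' @param areas named distal per-subtendon areas (mm^2), e.g. from
#'   [distal_areas()].
#' @return a data.frame (one row per model spec) with columns `cohort`,
#'   `ratio`, `twist_deg`, `increment`, `total_force`, and per-subtendon
#'   stresses (Pa) and forces (N).
#' @export
build_batch <- function(cohorts = c(uniform = 1, soleus_doubled = 2,
                                    soleus_halved = 0.5),
                        twist_grid = seq(0, 180, by = 10),
                        profile, areas) {
  stopifnot(inherits(profile, "gait_profile"))
  if (length(twist_grid) < 1) stop("'twist_grid' must be non-empty")
  if (length(cohorts) < 1) stop("'cohorts' must be non-empty")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("ratio_", cohorts)
  rows <- vector("list", length(cohorts) * length(twist_grid))
  i <- 0
  for (ci in seq_along(cohorts)) {
    for (tw in twist_grid) {
      inc <- seq_len(profile$n_increments)
      sg <- vapply(profile$total_force, function(f)
        partition_cohort_forces(f, areas, cohorts[[ci]])$stress, numeric(3))
      i <- i + 1
      rows[[i]] <- data.frame(
        cohort = names(cohorts)[ci], ratio = cohorts[[ci]],
        twist_deg = tw, increment = inc,
        total_force = profile$total_force,
        sigma_LG = sg["LG", ], sigma_MG = sg["MG", ], sigma_S = sg["S", ],
        force_LG = sg["LG", ] * areas[["LG"]] * 1e-6,
        force_MG = sg["MG", ] * areas[["MG"]] * 1e-6,
        force_S = sg["S", ] * areas[["S"]] * 1e-6)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
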