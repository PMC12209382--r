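# Health-state and fracture-site vocabulary shared by every module.

#' Fracture sites and health states
#'
#' The model distinguishes four osteoporotic fracture sites ordered by a
#' severity hierarchy (hip > vertebral > wrist > other, rank 1 being most
#' severe) and eight health states: well, one acute state per fracture site,
#' two chronic post-fracture states (post hip, post vertebral) and dead.
#' Wrist and other fractures have no chronic state; survivors return to well
#' after the acute phase.
#'
#' @return `fracture_sites()` returns a tibble with columns `site` and
#'   `rank`; `health_states()` returns a character vector of the eight state
#'   names.
#' @export
#' @examples
#' fracture_sites()
#' health_states()
fracture_sites <- function() {
  tibble::tibble(
    site = c("hip", "vertebral", "wrist", "other"),
    rank = 1:4
  )
}

#' @rdname fracture_sites
#' @export
health_states <- function() {
  c("well", "hip_fx", "vert_fx", "wrist_fx", "other_fx",
    "post_hip", "post_vert", "dead")
}

# Integer codes used by the cycle engines (kept internal; the user-facing
# surface always speaks site/state names).
.SITES <- c("hip", "vertebral", "wrist", "other")
.ST <- c(well = 1L, hip_fx = 2L, vert_fx = 3L, wrist_fx = 4L, other_fx = 5L,
         post_hip = 6L, post_vert = 7L)

# clock semantics by state:
#   well      : 0 = no recent "other" fracture, 2..16 = cycles since an
#               "other" fracture (the 8-year excess-mortality window)
#   hip_fx, vert_fx : always 0 (acute, one cycle unless same-site re-fracture)
#   wrist_fx, other_fx : 0 acute, 1 convalescent (second half of the 1-year
#               cost/disutility window; routes like well)
#   post_hip, post_vert : 1..15 = cycles since fracture (excess mortality
#               applies through 15), 16 = beyond the 8-year window
.CLOCK_MAX <- 16L
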