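#' Pairwise social interaction kernels
#'
#' The heading change a neighbor induces on a focal fish at a kick onset is
#' the sum of an attraction term and an alignment term, each a product of
#' decoupled functions of the relative state `(d, psi, phi)`:
#' distance `d`, viewing angle `psi` (angle at which the focal fish perceives
#' the neighbor, measured from its own heading) and relative heading
#' `phi = phi_neighbor - phi_focal`:
#'
#' \deqn{\delta\varphi = F_{Att}(d)\,O_{Att}(\psi)\,E_{Att}(\phi) +
#'       F_{Ali}(d)\,E_{Ali}(\psi)\,O_{Ali}(\phi)}
#'
#' with the *H. rhodostomus* kernels
#' \deqn{F_{Att}(d) = \gamma_{Att}\,\frac{d/d_{Att} - 1}{1 + (d/l_{Att})^2}}
#' \deqn{O_{Att}(\psi) = 1.395\,\sin\psi\,(1 - 0.33\cos\psi)}
#' \deqn{E_{Att}(\phi) = 0.9326\,(1 - 0.48\cos\phi - 0.31\cos 2\phi)}
#' \deqn{F_{Ali}(d) = \gamma_{Ali}\,(d/d_{Ali} + 1)\,e^{-(d/l_{Ali})^2}}
#' \deqn{E_{Ali}(\psi) = 0.9012\,(1 + 0.6\cos\psi - 0.32\cos 2\psi)}
#' \deqn{O_{Ali}(\phi) = 1.6385\,\sin\phi\,(1 + 0.3\cos 2\phi)}
#'
#' `O` factors are odd, `E` factors even, so the social turn flips sign under
#' mirror reflection of the configuration about the focal heading axis.
#' Attraction is repulsive below `d_att` (F negative), vanishes at `d_att`,
#' and decays like 1/d at long range; alignment is Gaussian-suppressed beyond
#' `l_ali`. All functions are vectorized over their first argument.
#'
#' @param d inter-fish distance, metres, >= 0.
#' @param psi viewing angle, radians.
#' @param phi relative heading, radians.
#' @param params an [interaction_params()] object.
#' @return numeric vector of kernel values.
#' @examples
#' p <- interaction_params()
#' f_att(p$d_att, p)   # exactly 0 at the repulsion crossover
#' f_att(0, p)         # -gamma_att: hard repulsion at contact
#' o_att(pi / 2)       # lateral neighbors pull hardest
#' @name interaction_kernels
NULL

#' @rdname interaction_kernels
#' @export
f_att <- function(d, params) {
  params$gamma_att * (d / params$d_att - 1) / (1 + (d / params$l_att)^2)
}

#' @rdname interaction_kernels
#' @export
o_att <- function(psi) 1.395 * sin(psi) * (1 - 0.33 * cos(psi))

#' @rdname interaction_kernels
#' @export
e_att <- function(phi) 0.9326 * (1 - 0.48 * cos(phi) - 0.31 * cos(2 * phi))

#' @rdname interaction_kernels
#' @export
f_ali <- function(d, params) {
  params$gamma_ali * (d / params$d_ali + 1) * exp(-(d / params$l_ali)^2)
}

#' @rdname interaction_kernels
#' @export
e_ali <- function(psi) 0.9012 * (1 + 0.6 * cos(psi) - 0.32 * cos(2 * psi))

#' @rdname interaction_kernels
#' @export
o_ali <- function(phi) 1.6385 * sin(phi) * (1 + 0.3 * cos(2 * phi))

#' Relative state of a neighbor with respect to a focal fish
#'
#' Computes the triplet `(d, psi, phi)` used by the interaction kernels:
#' Euclidean distance, viewing angle (angle of the focal-to-neighbor vector
#' minus the focal heading) and relative heading, both wrapped to (-pi, pi].
#' Coincident positions (`d == 0`) leave the viewing angle undefined; the
#' convention `psi = 0` is used and the state is flagged `degenerate`
#' (`O_att(0) = 0` then zeroes the attraction term, and the sub-`d_att`
#' repulsion makes such states transient).
#'
#' @param focal_position,neighbor_position numeric length-2 positions, metres.
#' @param focal_heading,neighbor_heading headings, radians.
#' @return list with components `d`, `psi`, `phi`, `degenerate`.
#' @examples
#' relative_state(c(0, 0), 0, c(0, 1), 0)  # neighbor to the left: psi = pi/2
#' @export
relative_state <- function(focal_position, focal_heading,
                           neighbor_position, neighbor_heading) {
  dx <- neighbor_position[1] - focal_position[1]
  dy <- neighbor_position[2] - focal_position[2]
  d <- sqrt(dx * dx + dy * dy)
  degenerate <- d == 0
  psi <- if (degenerate) 0 else wrap_angle(atan2(dy, dx) - focal_heading)
  list(d = d,
       psi = psi,
       phi = wrap_angle(neighbor_heading - focal_heading),
       degenerate = degenerate)
}

#' Social heading-change contribution of one neighbor
#'
#' Attraction plus alignment turn induced by a neighbor in relative state
#' `rel`, in radians. See [interaction_kernels] for the functional forms.
#'
#' @param rel a relative state as returned by [relative_state()], or a list
#'   with numeric components `d`, `psi`, `phi` (vectors of equal length are
#'   accepted).
#' @param params an [interaction_params()] object.
#' @return heading change contribution, radians.
#' @examples
#' p <- interaction_params()
#' rel <- relative_state(c(0, 0), 0, c(0, 0.2), 0)
#' pairwise_turn(rel, p)
#' @export
pairwise_turn <- function(rel, params) {
  f_att(rel$d, params) * o_att(rel$psi) * e_att(rel$phi) +
    f_ali(rel$d, params) * e_ali(rel$psi) * o_ali(rel$phi)
}

#' Influence of a neighbor on a focal fish
#'
#' The influence is the absolute value of the neighbor's contribution to the
#' focal fish's instantaneous heading change, `|pairwise_turn(rel)|`. It
#' weighs distance, the anisotropy of perception (viewing angle) and the
#' degree of alignment; a lateral neighbor typically exerts more influence
#' than one dead ahead at the same distance.
#'
#' @inheritParams pairwise_turn
#' @return nonnegative influence score.
#' @export
influence <- function(rel, params) abs(pairwise_turn(rel, params))

#' Select the k most influential neighbors
#'
#' Ranks all neighbors of a focal fish by influence (descending) and returns
#' the top `min(k, N - 1)`. Ties are broken by ascending fish identifier
#' (stable, reproducible). With `N = 1` the selection is empty and the social
#' term of the kick update vanishes.
#'
#' @param focal_index index (1-based) of the focal fish.
#' @param positions N x 2 matrix of positions, metres.
#' @param headings length-N vector of headings, radians.
#' @param params an [interaction_params()] object; `params$k` neighbors are
#'   selected.
#' @return list with `ids` (selected neighbor indices, influence-descending),
#'   `influence` (their scores) and `rel` (list of their relative states).
#' @examples
#' pos <- rbind(c(0, 0), c(0.1, 0.1), c(-0.2, 0))
#' select_influential(1, pos, c(0, 0, pi / 2), interaction_params(k = 2))
#' @export
select_influential <- function(focal_index, positions, headings, params) {
  n <- nrow(positions)
  others <- setdiff(seq_len(n), focal_index)
  if (length(others) == 0L)
    return(list(ids = integer(0), influence = numeric(0), rel = list()))
  rel <- lapply(others, function(j)
    relative_state(positions[focal_index, ], headings[focal_index],
                   positions[j, ], headings[j]))
  inf <- vapply(rel, influence, numeric(1), params = params)
  # order by influence descending, fish id ascending on ties
  ord <- order(-inf, others)
  take <- seq_len(min(params$k, length(others)))
  sel <- ord[take]
  list(ids = others[sel], influence = inf[sel], rel = rel[sel])
}
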