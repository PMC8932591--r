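#' Analytic school configurations for testing
#'
#' Small deterministic snapshots with known observable values, used to test
#' the kernels and order parameters:
#' * `"ring"`: `n` fish evenly spaced on a circle, moving tangentially
#'   (counter-clockwise by default) at equal speed; milling index exactly 1,
#'   barycenter velocity 0.
#' * `"line"`: `n` fish on a straight line with a common heading;
#'   polarization exactly 1.
#' * `"mirror_pair"`: two fish mirror-symmetric about the x axis; the social
#'   turns they induce on each other are equal and opposite in sign.
#' * `"antiparallel"`: half the fish heading North, half South;
#'   polarization exactly 0 (for even `n`).
#'
#' @param type configuration type.
#' @param n number of fish.
#' @param radius ring radius, metres.
#' @param spacing line spacing, metres.
#' @param speed common speed, m/s.
#' @param heading common heading for `"line"`, radians.
#' @param clockwise rotate the ring clockwise instead?
#' @param time snapshot time stamp.
#' @return a [school_snapshot()].
#' @examples
#' milling(school_fixture("ring", n = 4))       # exactly 1
#' polarization(school_fixture("line", n = 5))  # exactly 1
#' @export
school_fixture <- function(type = c("ring", "line", "mirror_pair",
                                    "antiparallel"),
                           n = 4L, radius = 1, spacing = 0.1, speed = 0.14,
                           heading = 0, clockwise = FALSE, time = 0) {
  type <- match.arg(type)
  switch(type,
    ring = {
      th <- 2 * pi * (seq_len(n) - 1) / n
      hd <- wrap_angle(th + if (clockwise) -pi / 2 else pi / 2)
      school_snapshot(time, radius * cbind(cos(th), sin(th)), hd,
                      rep(speed, n))
    },
    line = {
      school_snapshot(time,
                      cbind(spacing * (seq_len(n) - 1), numeric(n)),
                      rep(heading, n), rep(speed, n))
    },
    mirror_pair = {
      school_snapshot(time, rbind(c(0, spacing), c(0, -spacing)),
                      wrap_angle(c(heading, -heading)), rep(speed, 2))
    },
    antiparallel = {
      hd <- rep(c(pi / 2, -pi / 2), length.out = n)
      school_snapshot(time, cbind(spacing * (seq_len(n) - 1), numeric(n)),
                      hd, rep(speed, n))
    })
}
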