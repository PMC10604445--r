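#' Endplate landmark pairs for a lordosis measurement
#'
#' @param L1_superior,S1_superior 2x2 numeric matrices, one landmark point per
#'   row, defining the superior endplate line of L1 and of S1 on a lateral
#'   radiograph. The two points of a pair must be distinct.
#' @return object of class `endplate_landmarks`.
#' @export
endplate_landmarks <- function(L1_superior, S1_superior) {
  chk <- function(p, name) {
    p <- as.matrix(p)
    if (!all(dim(p) == c(2, 2))) stop(name, " must be a 2x2 point matrix")
    if (all(p[1, ] == p[2, ])) stop("coincident landmark points in ", name)
    p
  }
  structure(list(L1_superior = chk(L1_superior, "L1_superior"),
                 S1_superior = chk(S1_superior, "S1_superior")),
            class = "endplate_landmarks")
}

#' Cobb angle between the superior endplates of L1 and S1
#'
#' Lumbar lordosis as the unsigned angle, in degrees within \eqn{[0, 90]},
#' between the two endplate lines.
#'
#' @param landmarks an [endplate_landmarks()].
#' @return angle in degrees.
#' @export
cobb_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "endplate_landmarks"))
  u <- landmarks$L1_superior[2, ] - landmarks$L1_superior[1, ]
  v <- landmarks$S1_superior[2, ] - landmarks$S1_superior[1, ]
  cosang <- abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(min(1, max(0, cosang))) * 180 / pi
}
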