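#' Fit an affine channel registration
#'
#' Least-squares estimate of the 2D affine map (2x2 linear part plus
#' translation) taking the moving channel's fiducial coordinates onto the
#' reference channel's: `ref ~ A %*% mov + shift`, fit by ordinary least
#' squares over paired points. When a grouping label is supplied (one label
#' per recording of fiducial beads), the target registration error is
#' estimated by leaving one recording out at a time, refitting, and taking
#' the RMS distance of the held-out mapped points to their references.
#'
#' @param ref,mov n x 2 matrices of paired coordinates (nm).
#' @param group optional vector of recording labels for leave-one-out TRE.
#' @return an [AffineMap2D-class].
#' @examples
#' set.seed(1)
#' mov <- matrix(runif(20, 0, 1e4), 10)
#' A <- matrix(c(cos(0.1), sin(0.1), -sin(0.1), cos(0.1)) * 1.01, 2)
#' ref <- mov %*% t(A) + 50
#' fitAffineRegistration(ref, mov)
#' @export
fitAffineRegistration <- function(ref, mov, group = NULL) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 2L || ncol(mov) != 2L)
    .stopf("ref and mov must be paired n x 2 matrices")
  fit <- .affineLS(ref, mov)
  resid <- ref - .affineApply(fit, mov)
  rms <- sqrt(mean(rowSums(resid^2)))
  tre <- NULL
  if (!is.null(group)) {
    group <- as.factor(group)
    if (nlevels(group) >= 2L) {
      sq <- 0; ntot <- 0L
      for (g in levels(group)) {
        hold <- group == g
        f <- .affineLS(ref[!hold, , drop = FALSE], mov[!hold, , drop = FALSE])
        dd <- ref[hold, , drop = FALSE] -
          .affineApply(f, mov[hold, , drop = FALSE])
        sq <- sq + sum(dd^2)
        ntot <- ntot + sum(hold)
      }
      tre <- sqrt(sq / ntot)
    }
  }
  new("AffineMap2D", A = fit$A, shift = fit$shift, rms = rms, tre = tre,
      nPoints = nrow(ref))
}

.affineLS <- function(ref, mov) {
  if (nrow(ref) < 3L) .stopf("need at least 3 point pairs")
  X <- cbind(mov, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L) .stopf("points are collinear; affine fit is degenerate")
  beta <- qr.coef(qrX, ref)              # 3 x 2
  list(A = t(beta[1:2, , drop = FALSE]), shift = as.numeric(beta[3L, ]))
}

.affineApply <- function(fit, pts) {
  sweep(pts %*% t(fit$A), 2L, fit$shift, `+`)
}

#' Apply or invert an affine map
#'
#' @param map an [AffineMap2D-class].
#' @param pts n x 2 matrix of coordinates (nm).
#' @return transformed coordinates / the inverse [AffineMap2D-class].
#' @export
applyAffineMap <- function(map, pts) {
  stopifnot(is(map, "AffineMap2D"))
  .affineApply(list(A = map@A, shift = map@shift), as.matrix(pts))
}

#' @rdname applyAffineMap
#' @export
invertAffineMap <- function(map) {
  stopifnot(is(map, "AffineMap2D"))
  Ai <- solve(map@A)
  new("AffineMap2D", A = Ai, shift = as.numeric(-Ai %*% map@shift),
      rms = map@rms, tre = map@tre, nPoints = map@nPoints)
}
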