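#' 12-parameter affine registration by sum-of-squared-differences
#'
#' Estimates the `affine12` transform that, applied to `moving` (pull-back
#' resampling onto the fixed grid), minimises the mean squared intensity
#' difference to `fixed`. Multi-resolution with staged degrees of freedom:
#' block-averaged pyramids at the given downsampling factors; at the
#' coarsest level the rigid (6-parameter) subproblem is solved from a small
#' multi-start over rotations (quasi-symmetric heads make single-start SSD
#' rotation estimates unreliable), finer levels refine the rigid solution,
#' and the full 12-parameter affine is released at the finest level only.
#' Intended for same-subject diffusion series; a global intensity
#' normalisation (on by default) equalises mean absolute intensity so a b=0
#' reference can serve as the fixed image.
#'
#' @param moving,fixed Volumes with overlapping world extent.
#' @param factors Integer downsampling factors, coarse to fine.
#' @param max_iter Iteration cap for the coarse/mid levels (the finest level
#'   is capped at `max_iter / 4` per stage).
#' @param tol Convergence tolerance on the relative cost decrease.
#' @param normalize Scale `moving` to match the mean absolute intensity of
#'   `fixed` before matching (default `TRUE`).
#' @param rigid_only If `TRUE`, scales and shears stay frozen at identity.
#' @param rotation_starts Rotation multi-start magnitude at the coarsest
#'   level, degrees (0 disables the extra starts).
#' @return An `affine12` transform (attributes: `cost`, the final mean
#'   squared difference per voxel; `center`, the rotation center used).
#' @export
register_affine <- function(moving, fixed, factors = c(4, 2, 1),
                            max_iter = 100, tol = 1e-6, normalize = TRUE,
                            rigid_only = FALSE, rotation_starts = 2) {
  stopifnot(is_volume(moving), is_volume(fixed))
  if (any(!is.finite(moving$data)) || any(!is.finite(fixed$data)))
    stop("non-finite values in input volumes")
  mov <- moving
  if (normalize) {
    sm <- mean(abs(mov$data)); sf <- mean(abs(fixed$data))
    if (sm <= 0 || sf <= 0) stop("empty image: cannot normalise intensities")
    mov$data <- mov$data * (sf / sm)
  }
  center <- center_world(fixed)
  scales <- c(rep(1, 6), rep(0.02, 6))   # mm/deg vs unitless sensitivities
  factors <- sort(unique(as.integer(factors)), decreasing = TRUE)

  stride_grid <- function(vol, s) {
    d <- dim(vol$data)
    idx <- lapply(d, function(n) seq(1L, n, by = s))
    aff <- vol$affine
    aff[1:3, 1:3] <- aff[1:3, 1:3] * s
    aff[1:3, 4] <- (vol$affine %*% c(0, 0, 0, 1))[1:3]
    volume(vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
           affine = aff)
  }
  level_cost <- function(f, sparse = FALSE) {
    if (sparse) {
      # finest level: full-resolution moving image, sparse fixed samples
      mv <- mov
      fx <- stride_grid(fixed, 2L)
    } else {
      mv <- block_mean(mov, f)
      fx <- block_mean(fixed, f)
    }
    mv_dat <- as.numeric(mv$data); mv_dim <- as.integer(dim(mv$data))
    fx_dat <- as.numeric(fx$data); fx_dim <- as.integer(dim(fx$data))
    inv_mov <- solve(mv$affine); fx_aff <- fx$affine
    n_vox <- length(fx_dat)
    function(p) {
      if (any(p[7:9] <= 0)) return(1e30)
      M <- inv_mov %*% affine_matrix(p, center) %*% fx_aff
      ssd_affine_cpp(mv_dat, mv_dim, M, fx_dat, fx_dim) / n_vox
    }
  }
  run <- function(cost, par, free, maxit) {
    fn_raw <- function(q) {
      p <- par; p[free] <- q; cost(p)
    }
    last <- new.env()
    fn <- function(q) {
      v <- fn_raw(q)
      last$q <- q; last$v <- v
      v
    }
    h <- 1e-2 * scales[free]
    gr <- function(q) {   # forward differences, reusing the cached f(q)
      v0 <- if (!is.null(last$q) && identical(last$q, q)) last$v else fn(q)
      vapply(seq_along(q), function(i) {
        qq <- q; qq[i] <- qq[i] + h[i]
        (fn_raw(qq) - v0) / h[i]
      }, numeric(1))
    }
    opt <- stats::optim(par[free], fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = tol / 1e-15,
                                       parscale = scales[free]))
    par[free] <- opt$par
    attr(par, "value") <- opt$value
    par
  }

  par <- as.numeric(affine_identity())
  # rotation multi-start runs at the mid level: the coarsest block-averaged
  # level aliases in-plane rotations on a quasi-symmetric head
  ms_level <- max(1L, length(factors) - 1L)
  for (li in seq_along(factors)) {
    f <- factors[li]
    finest <- li == length(factors)
    cost <- level_cost(f, sparse = finest && f == 1L)
    maxit <- if (finest) max(12, max_iter %/% 5) else
      if (li == 1L) max_iter %/% 2 else max_iter %/% 3
    if (li == ms_level && rotation_starts > 0) {
      a <- rotation_starts
      offsets <- list(c(0, 0, 0), c(a, a, a), c(-a, -a, -a),
                      c(a, -a, a), c(-a, a, -a), c(0, 0, a), c(0, 0, -a))
      # short ranking pass per start, full budget for the winner
      cands <- lapply(offsets, function(r) {
        p0 <- par; p0[4:6] <- par[4:6] + r
        run(cost, p0, 1:6, 8)
      })
      vals <- vapply(cands, attr, numeric(1), "value")
      par <- as.numeric(run(cost, as.numeric(cands[[which.min(vals)]]),
                            1:6, maxit))
    } else {
      par <- as.numeric(run(cost, par, 1:6, maxit))
    }
    if (finest && !rigid_only) {
      res <- run(cost, par, 1:12, maxit)
      final_value <- attr(res, "value")
      par <- as.numeric(res)
    } else if (finest) {
      res <- run(cost, par, 1:6, 1)  # evaluate converged cost
      final_value <- attr(res, "value")
    }
  }
  out <- affine_params(par[1:3], par[4:6], par[7:9], par[10:12])
  attr(out, "cost") <- final_value
  attr(out, "center") <- center
  out
}
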