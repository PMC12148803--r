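# Loss components of the adversarial translation objective.
#
# Conventions: every squared-norm term is the MEAN of squared elements over a
# score map (and over the batch), and every l1 term the mean of absolute
# pixel differences. Means rather than sums keep the loss magnitudes
# independent of image and map size, so the published weights (lambda_c = 10,
# lambda_i = 5) stay balanced at reduced resolution.

#' Loss weights for the generator objective
#'
#' `lambda_c` and `lambda_i` weight the cycle-consistency and identity terms
#' (published values 10 and 5). `lambda_s` weights the symmetry term through
#' which the similarity discriminator reaches the generators; `lambda_s = 0`
#' reproduces a plain cycle-GAN.
#'
#' @param lambda_c Cycle-consistency weight (default 10).
#' @param lambda_i Identity weight (default 5).
#' @param lambda_s Symmetry weight (default 1).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_c = 10, lambda_i = 5, lambda_s = 1) {
  if (lambda_c < 0 || lambda_i < 0 || lambda_s < 0)
    stop("loss weights must be nonnegative")
  structure(list(lambda_c = lambda_c, lambda_i = lambda_i,
                 lambda_s = lambda_s), class = "loss_weights")
}

check_finite <- function(..., what = "loss input") {
  for (x in list(...))
    if (!all(is.finite(x))) stop("non-finite values in ", what)
  invisible(TRUE)
}

mean_sq <- function(x) mean(x * x)
mean_abs <- function(a, b) {
  if (!identical(dim(a), dim(b)) && length(a) != length(b))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  mean(abs(a - b))
}

#' Adversarial (least-squares) generator loss
#'
#' `mean((D_y(G_xy(x)) - 1)^2) + mean((D_x(G_yx(y)) - 1)^2)`: zero exactly
#' when both discriminators score the synthetic slices as fully real (all
#' ones).
#'
#' @param Dy_of_fake_y,Dx_of_fake_x Discriminator score maps for the
#'   synthetic healthy and synthetic unhealthy slices.
#' @return Nonnegative scalar.
#' @export
gan_loss <- function(Dy_of_fake_y, Dx_of_fake_x) {
  check_finite(Dy_of_fake_y, Dx_of_fake_x, what = "discriminator score map")
  mean_sq(Dy_of_fake_y - 1) + mean_sq(Dx_of_fake_x - 1)
}

#' Cycle-consistency loss
#'
#' Mean absolute error between each slice and its round-trip reconstruction
#' through both generators, summed over the two directions.
#'
#' @param x,x_reconstructed Unhealthy slices and their reconstructions
#'   `G_yx(G_xy(x))`.
#' @param y,y_reconstructed Healthy slices and their reconstructions
#'   `G_xy(G_yx(y))`.
#' @return Nonnegative scalar; zero iff both reconstructions are exact.
#' @export
cycle_loss <- function(x, x_reconstructed, y, y_reconstructed) {
  mean_abs(x_reconstructed, x) + mean_abs(y_reconstructed, y)
}

#' Identity loss
#'
#' Penalizes a generator for altering an image already in its target domain:
#' `mean|G_xy(y) - y| + mean|G_yx(x) - x|`. This keeps changes confined to
#' the tumor region.
#'
#' @param x Unhealthy slices; `Gyx_of_x` is `G_yx(x)`.
#' @param y Healthy slices; `Gxy_of_y` is `G_xy(y)`.
#' @param Gyx_of_x,Gxy_of_y Generator outputs on their own target domains.
#' @return Nonnegative scalar.
#' @export
identity_loss <- function(x, Gyx_of_x, y, Gxy_of_y) {
  mean_abs(Gxy_of_y, y) + mean_abs(Gyx_of_x, x)
}

#' Discriminator loss
#'
#' Least-squares targets: synthetic slices should score 0, real slices 1,
#' for both `D_x` and `D_y`.
#'
#' @param Dx_fake Score map `D_x(G_yx(y))`.
#' @param Dy_fake Score map `D_y(G_xy(x))`.
#' @param Dy_real Score map `D_y(y)`.
#' @param Dx_real Score map `D_x(x)`.
#' @return Nonnegative scalar; zero iff fakes score 0 and reals score 1.
#' @export
discriminator_loss <- function(Dx_fake, Dy_fake, Dy_real, Dx_real) {
  check_finite(Dx_fake, Dy_fake, Dy_real, Dx_real,
               what = "discriminator score map")
  mean_sq(Dx_fake) + mean_sq(Dy_fake) +
    mean_sq(Dy_real - 1) + mean_sq(Dx_real - 1)
}

#' Similarity (bilateral symmetry) discriminator loss
#'
#' For each slice the similarity discriminator produces a scalar symmetry
#' score `s = mean(D_smi(left)) - mean(D_smi(mirrored right))` (see
#' [smi_score()]). Healthy slices - real `y` and synthetic `y'` - should
#' look symmetric (`s` near 0); unhealthy slices - real `x` and synthetic
#' `x'` - should look asymmetric (`|s|` near 1). The loss is the sum of the
#' batch-mean terms `s^2` over healthy inputs and `(|s| - 1)^2` over
#' unhealthy inputs.
#'
#' @param real_healthy,fake_healthy,real_unhealthy,fake_unhealthy Slice
#'   tensors `(H, W, 1, N)` (or matrices) with even width.
#' @param D_smi The similarity discriminator network.
#' @return Nonnegative scalar; zero at the stated optimum.
#' @export
similarity_loss <- function(real_healthy, fake_healthy, real_unhealthy,
                            fake_unhealthy, D_smi) {
  s_y <- smi_score(D_smi, real_healthy)$s
  s_yp <- smi_score(D_smi, fake_healthy)$s
  s_x <- smi_score(D_smi, real_unhealthy)$s
  s_xp <- smi_score(D_smi, fake_unhealthy)$s
  check_finite(s_y, s_yp, s_x, s_xp, what = "symmetry score")
  mean(s_y^2) + mean(s_yp^2) +
    mean((abs(s_x) - 1)^2) + mean((abs(s_xp) - 1)^2)
}

#' Total generator objective
#'
#' `l_gan + lambda_c * l_cycle + lambda_i * l_id + lambda_s * symmetry_term`.
#' With `lambda_s = 0` this is the plain cycle-GAN generator objective.
#'
#' @param l_gan,l_cycle,l_id Nonnegative loss components.
#' @param symmetry_term Generator-side symmetry penalty (pushes synthetic
#'   healthy toward `s = 0` and synthetic unhealthy toward `|s| = 1`);
#'   default 0.
#' @param weights A [loss_weights()] object.
#' @return Scalar total.
#' @export
generator_total <- function(l_gan, l_cycle, l_id, symmetry_term = 0,
                            weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  if (any(c(l_gan, l_cycle, l_id, symmetry_term) < 0))
    stop("loss components must be nonnegative")
  l_gan + weights$lambda_c * l_cycle + weights$lambda_i * l_id +
    weights$lambda_s * symmetry_term
}
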