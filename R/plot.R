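#' Time-series plot of a simulated system
#'
#' Time on the x-axis, component levels on the y-axis, one labeled line
#' per component — the standard way of inspecting theory-implied data.
#'
#' @param traj A `facsim_trajectory`.
#' @param components Character vector of component names (state or
#'   exogenous); default all state components.
#' @param path Optional PNG output path; when `NULL`, draws on the
#'   current device.
#' @param main Plot title.
#' @return `path` (or `NULL`) invisibly.
#' @export
plot_timeseries <- function(traj, components = NULL, path = NULL,
                            main = "Simulated system behavior") {
  all_mat <- cbind(traj$states, traj$exogenous)
  if (is.null(components)) components <- colnames(traj$states)
  missing <- setdiff(components, colnames(all_mat))
  if (length(missing))
    stop("unknown component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- all_mat[, components, drop = FALSE]
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 560)
    on.exit(grDevices::dev.off())
  }
  cols <- grDevices::hcl.colors(max(3, ncol(m)), "Dark 3")[seq_len(ncol(m))]
  graphics::matplot(traj$times, m, type = "l", lty = 1, lwd = 2,
                    col = cols, xlab = "time (arbitrary units)",
                    ylab = "level (arbitrary units)", main = main)
  graphics::legend("topleft", legend = components, col = cols, lty = 1,
                   lwd = 2, bty = "n")
  invisible(path)
}

#' Three-dimensional phase portrait
#'
#' Projects the trajectory of three components into a 3D box, drawing
#' the path over time with a white square marking the start and a black
#' square marking the end of the trajectory. The default axes are panic,
#' avoidant coping, and the credibility of the catastrophic
#' interpretation.
#'
#' @param traj A `facsim_trajectory`.
#' @param axes Character vector of exactly 3 state-component names.
#' @param path Optional PNG output path.
#' @param theta,phi Viewing angles passed to [graphics::persp()].
#' @return `path` (or `NULL`) invisibly.
#' @export
plot_phase_portrait <- function(traj, axes = c("Re", "Rb", "cred_cat"),
                                path = NULL, theta = 40, phi = 25) {
  stopifnot(length(axes) == 3L)
  missing <- setdiff(axes, colnames(traj$states))
  if (length(missing))
    stop("unknown component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- traj$states[, axes[1]]
  y <- traj$states[, axes[2]]
  z <- traj$states[, axes[3]]
  pad <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    r + c(-0.05, 0.05) * diff(r)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  pm <- graphics::persp(x = pad(x), y = pad(y),
                        z = matrix(c(NA, NA, NA, NA), 2, 2),
                        xlim = pad(x), ylim = pad(y), zlim = pad(z),
                        xlab = axes[1], ylab = axes[2], zlab = axes[3],
                        theta = theta, phi = phi, border = NA,
                        ticktype = "detailed",
                        main = "Phase portrait (white = start, black = end)")
  pts <- grDevices::trans3d(x, y, z, pm)
  graphics::lines(pts$x, pts$y, col = "steelblue", lwd = 1.5)
  start <- grDevices::trans3d(x[1], y[1], z[1], pm)
  end <- grDevices::trans3d(x[length(x)], y[length(y)], z[length(z)], pm)
  graphics::points(start$x, start$y, pch = 22, bg = "white", cex = 1.6)
  graphics::points(end$x, end$y, pch = 22, bg = "black", cex = 1.6)
  invisible(path)
}
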