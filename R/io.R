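#' Write a press trial to a trial directory
#'
#' Lays a trial out on disk in the exchange format consumed by the image
#' pipeline: `ridge/frame_%05d.tif` and `contact/frame_%05d.tif` (8-bit
#' grayscale TIFF), `force.csv` (columns `t_s`, `fx_N`, `fy_N`, `fz_N`),
#' `frames.csv` (frame timestamps and synchronized forces) and `meta.yaml`
#' (vibration amplitude, friction coefficient, pixel resolution, frame
#' rate). Images are quantised to 8 bits by the generator, so a write/read
#' cycle is lossless.
#'
#' @param trial A `press_trial`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(file.path(dir, "ridge"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "contact"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(trial$frames)) {
    fr <- trial$frames[[i]]
    tiff::writeTIFF(fr$ridge, file.path(dir, "ridge",
                                        sprintf("frame_%05d.tif", i)),
                    bits.per.sample = 8)
    tiff::writeTIFF(fr$contact, file.path(dir, "contact",
                                          sprintf("frame_%05d.tif", i)),
                    bits.per.sample = 8)
  }
  fcsv <- trial$force
  utils::write.csv(data.frame(t_s = sprintf("%.17g", fcsv$t_s),
                       fx_N = sprintf("%.17g", fcsv$fx_N),
                       fy_N = sprintf("%.17g", fcsv$fy_N),
                       fz_N = sprintf("%.17g", fcsv$fz_N)),
            file.path(dir, "force.csv"), row.names = FALSE, quote = FALSE)
  frames_tab <- data.frame(
    t_s = sprintf("%.17g", vapply(trial$frames, `[[`, numeric(1), "t_s")),
    fz_N = sprintf("%.17g", vapply(trial$frames, `[[`, numeric(1), "fz_N")))
  utils::write.csv(frames_tab, file.path(dir, "frames.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(trial$meta, file.path(dir, "meta.yaml"),
                   precision = 15)
  invisible(dir)
}

#' Read a press trial from a trial directory
#'
#' Inverse of [write_trial()]. The ground-truth record is not part of the
#' on-disk exchange format, so the returned trial has `truth = NULL`.
#'
#' @param dir Trial directory.
#' @return A `press_trial` (without `truth`).
#' @export
read_trial <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  force <- utils::read.csv(file.path(dir, "force.csv"))
  frames_tab <- utils::read.csv(file.path(dir, "frames.csv"))
  files <- sort(list.files(file.path(dir, "ridge"), pattern = "^frame_.*\\.tif$"))
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    rd <- tiff::readTIFF(file.path(dir, "ridge", files[i]))
    ct <- tiff::readTIFF(file.path(dir, "contact", files[i]))
    if (length(dim(rd)) == 3) rd <- rd[, , 1]
    if (length(dim(ct)) == 3) ct <- ct[, , 1]
    frames[[i]] <- list(ridge = rd, contact = ct,
                        t_s = frames_tab$t_s[i], fz_N = frames_tab$fz_N[i])
  }
  structure(list(frames = frames,
                 force = tibble::as_tibble(force),
                 meta = meta, truth = NULL),
            class = "press_trial")
}

#' @export
print.press_trial <- function(x, ...) {
  cat("Synthetic press trial:", length(x$frames), "frames,",
      x$meta$size_px %||% nrow(x$frames[[1]]$ridge), "px,",
      "alpha =", x$meta$alpha_um, "um, mu =", round(x$meta$mu, 3), "\n")
  fz <- vapply(x$frames, `[[`, numeric(1), "fz_N")
  cat(sprintf("  force %.2f -> %.2f N over %.2f s\n", fz[1], max(fz),
              x$frames[[length(x$frames)]]$t_s))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
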