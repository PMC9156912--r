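#' Write a trajectory to a plain-text file
#'
#' Format: header lines prefixed with `#` carrying one `key value` pair each
#' (time step, stride, seed, geometry and model parameters), followed by
#' whitespace-separated data rows `id frame x y` with 0-based frames and
#' positions in metres printed with four decimals (0.1 mm, below any model
#' scale, and diffable).
#'
#' @param trajectory a `ped_trajectory`.
#' @param path output file path.
#' @return The path, invisibly.
#' @seealso [read_trajectory()]
#' @export
write_trajectory <- function(trajectory, path) {
  g <- trajectory$geometry
  p <- trajectory$params
  hdr <- c(
    "format pedbottleneck-trajectory-v1",
    paste("n_agents", trajectory$n_agents),
    paste("n_frames", length(trajectory$times)),
    paste("dt", format(trajectory$dt, digits = 12)),
    paste("stride", trajectory$stride),
    paste("seed", if (is.null(trajectory$seed)) NA else trajectory$seed),
    paste("variant", g$variant),
    paste("b", format(g$b, digits = 12)),
    paste("l_c", format(g$l_c, digits = 12)),
    paste("w_e", format(g$w_e, digits = 12)),
    paste("exit_depth", format(g$exit_depth, digits = 12)),
    paste("v0", format(p$v0, digits = 12)),
    paste("l", format(p$l, digits = 12)),
    paste("T", format(p$T, digits = 12)),
    paste("sigma", format(p$sigma, digits = 12)),
    paste("sigma_is_variance", p$sigma_is_variance))
  if (!is.null(trajectory$exits) && nrow(trajectory$exits) > 0)
    hdr <- c(hdr, sprintf("exit %d %.6f", trajectory$exits$id,
                          trajectory$exits$time))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", hdr), con)
  nf <- length(trajectory$times)
  for (f in seq_len(nf)) {
    pos <- trajectory$pos[, , f, drop = FALSE]
    act <- which(!is.na(pos[, 1, 1]))
    if (length(act) == 0L) next
    writeLines(sprintf("%d %d %.4f %.4f", act, f - 1L,
                       pos[act, 1, 1], pos[act, 2, 1]), con)
  }
  invisible(path)
}

#' Read a trajectory file
#'
#' Parses the dialect written by [write_trajectory()] and rebuilds the
#' geometry and parameters from the header. Exit records are taken from the
#' `# exit id time` header lines when present (written by
#' [write_trajectory()]); otherwise they are recomputed with
#' [detect_exits()]. Malformed data rows raise an error naming the line
#' number.
#'
#' @param path trajectory file path.
#' @return A `ped_trajectory` object.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr, "\\s+")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = " "), "")
  exit_rows <- which(keys == "exit")
  exits_hdr <- NULL
  if (length(exit_rows)) {
    em <- do.call(rbind, lapply(kv[exit_rows], function(x)
      as.numeric(x[2:3])))
    ord <- order(em[, 2])
    exits_hdr <- data.frame(id = as.integer(em[ord, 1]), time = em[ord, 2])
  }
  h <- setNames(vals[keys != "exit"], keys[keys != "exit"])
  need <- c("n_agents", "dt", "stride", "variant", "b", "l_c", "w_e",
            "exit_depth", "v0", "l", "T", "sigma")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("trajectory header missing: ", paste(miss, collapse = ", "))

  num <- function(k) as.numeric(h[[k]])
  builder <- if (h[["variant"]] == "hopper") build_hopper else build_corridor
  geom <- builder(num("b"), num("l_c"), num("w_e"), num("exit_depth"))
  params <- model_params(
    v0 = num("v0"), l = num("l"), T = num("T"), sigma = num("sigma"),
    dt = num("dt"),
    sigma_is_variance = !identical(h[["sigma_is_variance"]], "FALSE"))

  data_lines <- which(!is_hdr & nzchar(trimws(lines)))
  n <- as.integer(h[["n_agents"]])
  stride <- as.integer(h[["stride"]])
  parts <- strsplit(trimws(lines[data_lines]), "\\s+")
  bad <- which(vapply(parts, length, 0L) != 4L)
  if (length(bad))
    stop("corrupt trajectory row at line ", data_lines[bad[1]],
         ": expected `id frame x y`")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 4L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- data_lines[which(rowSums(is.na(m)) > 0)[1]]
    stop("corrupt trajectory row at line ", bad, ": non-numeric field")
  }
  if (any(m[, 1] < 1 | m[, 1] > n))
    stop("trajectory row with agent id outside 1..", n)
  nf <- if (!is.null(h[["n_frames"]])) as.integer(h[["n_frames"]])
        else as.integer(max(m[, 2])) + 1L
  pos <- array(NA_real_, dim = c(n, 2L, nf))
  idx <- cbind(m[, 1], 1, m[, 2] + 1)
  pos[idx] <- m[, 3]
  idx[, 2] <- 2
  pos[idx] <- m[, 4]
  times <- (seq_len(nf) - 1L) * params$dt * stride

  traj <- structure(
    list(pos = pos, times = times, exits = NULL, n_agents = n,
         params = params, geometry = geom, dt = params$dt, stride = stride,
         n_exited = NA_integer_,
         seed = if (!is.null(h[["seed"]]) && h[["seed"]] != "NA")
           as.integer(h[["seed"]]) else NULL,
         diagnostics = list()),
    class = "ped_trajectory")
  traj$exits <- if (is.null(exits_hdr)) detect_exits(traj) else exits_hdr
  traj$n_exited <- nrow(traj$exits)
  traj
}

#' Detect exit crossings from recorded frames
#'
#' Scans consecutive frames for sign changes of `y` within the exit opening
#' and linearly interpolates the crossing time. For stride-1 trajectories
#' this reproduces the crossing times recorded during simulation (up to the
#' printed coordinate precision for file round-trips).
#'
#' @param trajectory a `ped_trajectory`.
#' @return Data frame `id`, `time`, ordered by crossing time.
#' @export
detect_exits <- function(trajectory) {
  n <- trajectory$n_agents
  nf <- length(trajectory$times)
  half <- trajectory$geometry$w_e / 2
  out_id <- integer(0)
  out_t <- numeric(0)
  y <- trajectory$pos[, 2, , drop = FALSE]
  x <- trajectory$pos[, 1, , drop = FALSE]
  for (i in seq_len(n)) {
    yi <- y[i, 1, ]
    cross <- which(yi[-nf] > 0 & yi[-1] <= 0 &
                     !is.na(yi[-nf]) & !is.na(yi[-1]))
    if (length(cross) == 0L) next
    f <- cross[1]
    frac <- yi[f] / (yi[f] - yi[f + 1])
    xs <- x[i, 1, f] + frac * (x[i, 1, f + 1] - x[i, 1, f])
    if (abs(xs) > half + 1e-6) next
    out_id <- c(out_id, i)
    out_t <- c(out_t,
               trajectory$times[f] + frac *
                 (trajectory$times[f + 1] - trajectory$times[f]))
  }
  ord <- order(out_t)
  data.frame(id = out_id[ord], time = out_t[ord])
}
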