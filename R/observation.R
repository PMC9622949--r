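#' Standard 60-channel montage labels (10-10 system)
#' @export
montage_60 <- function() c(
  "Fp1", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2")

#' Synthetic channel gain matrix
#'
#' A seeded stand-in for the head-model lead field: each source projects to
#' channels with smooth random weights (random loadings smoothed along the
#' channel ordering so neighbouring channels mix similarly). No channel row
#' is all-zero. Real electrode geometry is out of scope.
#'
#' @param network a [network_spec()].
#' @param channels channel label vector (default the 60-channel montage).
#' @param seed RNG seed for the mixing weights.
#' @param smooth half-width of the channel smoothing kernel.
#' @return channels x sources matrix with dimnames, class `gain_matrix`.
#' @export
gain_matrix <- function(network, channels = montage_60(), seed = 101L, smooth = 4L) {
  nc <- length(channels); ns <- network$n_sources
  W <- withr_seed(seed, matrix(stats::rnorm(nc * ns), nc, ns))
  k <- stats::dnorm(seq(-smooth, smooth), sd = smooth / 2)
  k <- k / sum(k)
  Ws <- apply(W, 2, function(col) {
    padded <- c(rev(col[seq_len(smooth)]), col, rev(col[nc - seq_len(smooth) + 1]))
    stats::filter(padded, k, sides = 2)[smooth + seq_len(nc)]
  })
  Ws <- Ws / sqrt(mean(Ws^2))
  zero <- rowSums(abs(Ws)) < 1e-12
  if (any(zero)) Ws[zero, 1] <- 1e-6
  structure(Ws, dimnames = list(channels, network$sources), class = c("gain_matrix", "matrix"))
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Per-subject evoked response container
#'
#' @param subject subject identifier. @param condition `"control"` or
#'   `"interference"`. @param data channels x samples amplitude matrix (uV)
#'   with channel rownames. @param rate sampling rate (Hz).
#' @param epoch_start epoch start relative to stimulus (ms).
#' @export
subject_erp <- function(subject, condition, data, rate, epoch_start = 0) {
  stopifnot(is.matrix(data), all(is.finite(data)), !is.null(rownames(data)))
  structure(list(subject = subject, condition = condition, data = data,
                 rate = rate, epoch_start = epoch_start),
            class = "subject_erp")
}

erp_times <- function(erp) {
  erp$epoch_start + (seq_len(ncol(erp$data)) - 1) * 1000 / erp$rate
}

#' Project source activity to channels and add sensor noise
#'
#' Channel data are `gain %*% vp` plus white Gaussian noise scaled so that
#' the channel-level signal-to-noise ratio (signal power = mean square of
#' the noiseless channel data) equals `snr_db`. `snr_db = Inf` adds no
#' noise; if the projected signal is identically zero, noise falls back to
#' the absolute floor `noise_floor` (standard deviation).
#'
#' @param states a `source_states` from [simulate_sources()].
#' @param gain a [gain_matrix()] whose columns match the source order.
#' @param snr_db channel SNR in decibels. @param subject,condition metadata
#'   for the returned [subject_erp()]. @param noise_floor SD used when the
#'   signal has zero power.
#' @return a [subject_erp()]; sampling rate is `1000 / dt` Hz.
#' @export
project_to_channels <- function(states, gain, snr_db = Inf,
                                subject = "s1", condition = states$condition,
                                noise_floor = 0.01) {
  if (is.na(snr_db) || snr_db == -Inf) stop("snr_db must be finite or +Inf")
  if (ncol(gain) != nrow(states$vp)) stop("gain/source dimension mismatch")
  Y <- unclass(gain) %*% states$vp
  if (is.finite(snr_db)) {
    p_sig <- mean(Y^2)
    sd_n <- if (p_sig > 0) sqrt(p_sig / 10^(snr_db / 10)) else noise_floor
    Y <- Y + matrix(stats::rnorm(length(Y), sd = sd_n), nrow(Y), ncol(Y))
  }
  rownames(Y) <- rownames(gain)
  subject_erp(subject, condition, Y, rate = 1000 / states$dt, epoch_start = 0)
}

#' Reduce channel data to principal spatial modes
#'
#' Projects a set of ERPs onto the top left-singular vectors of the pooled
#' (channels x all-samples) data matrix — the standard dimension reduction
#' applied before model inversion. The returned projector is orthonormal,
#' so projection followed by back-projection is idempotent.
#'
#' @param erps list of [subject_erp()] with identical channel sets.
#' @param n_modes number of spatial modes to keep (>= 1).
#' @return list: `projection` (channels x n_modes), `modes` (list of
#'   n_modes x samples matrices, one per input ERP), `variance_captured`
#'   (fraction), and `back_project(mode_data)`.
#' @export
reduce_spatial_modes <- function(erps, n_modes = 8) {
  if (n_modes < 1) stop("n_modes must be >= 1")
  pooled <- do.call(cbind, lapply(erps, function(e) e$data))
  if (n_modes > nrow(pooled)) stop("n_modes exceeds channel count")
  sv <- svd(pooled, nu = n_modes, nv = 0)
  U <- sv$u
  list(projection = U,
       modes = lapply(erps, function(e) crossprod(U, e$data)),
       variance_captured = sum(sv$d[seq_len(n_modes)]^2) / sum(sv$d^2),
       back_project = function(m) U %*% m)
}

#' Positive Potential peak features
#'
#' Per channel, the peak amplitude is the maximum amplitude inside the
#' analysis window (default 250-350 ms post-stimulus) and the latency is
#' the time of that maximum; ties resolve to the earliest sample.
#'
#' @param erp a [subject_erp()].
#' @param window length-2 numeric window in ms, within the epoch.
#' @return data.frame: subject, condition, channel, amplitude (uV),
#'   latency (ms).
#' @export
extract_pp_features <- function(erp, window = c(250, 350)) {
  t <- erp_times(erp)
  sel <- which(t >= window[1] & t <= window[2])
  if (!length(sel)) stop("empty analysis window")
  seg <- erp$data[, sel, drop = FALSE]
  idx <- apply(seg, 1, which.max)   # which.max takes the earliest tie
  data.frame(subject = erp$subject, condition = erp$condition,
             channel = rownames(erp$data),
             amplitude = seg[cbind(seq_len(nrow(seg)), idx)],
             latency = t[sel][idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired Wilcoxon condition tests per channel
#'
#' Two-sided Wilcoxon signed-rank test of interference vs control for each
#' channel, separately for peak amplitude and latency. Channels whose
#' paired differences are all zero get the degenerate p = 1 rather than an
#' error. Raw p-values are reported; Benjamini-Hochberg adjusted values are
#' appended for convenience.
#'
#' @param pp long feature table from [extract_pp_features()] rows for both
#'   conditions of every subject.
#' @return data.frame: channel, feature, statistic, p_value, p_adj.
#' @export
wilcoxon_condition_test <- function(pp) {
  stopifnot(all(c("control", "interference") %in% pp$condition))
  out <- do.call(rbind, lapply(split(pp, pp$channel), function(d) {
    do.call(rbind, lapply(c("amplitude", "latency"), function(f) {
      a <- d[d$condition == "interference", ]
      b <- d[d$condition == "control", ]
      a <- a[order(a$subject), f]; b <- b[order(b$subject), f]
      diffs <- a - b
      if (all(diffs == 0)) {
        data.frame(channel = d$channel[1], feature = f, statistic = NA_real_,
                   p_value = 1, stringsAsFactors = FALSE)
      } else {
        w <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
        data.frame(channel = d$channel[1], feature = f,
                   statistic = unname(w$statistic), p_value = w$p.value,
                   stringsAsFactors = FALSE)
      }
    }))
  }))
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Write / read ERP sets as long-format CSV
#'
#' Columns: subject, condition, channel, time_ms, amplitude_uv, rate_hz,
#' epoch_start_ms.
#'
#' @param erps list of [subject_erp()]. @param path CSV file path.
#' @export
write_erp_csv <- function(erps, path) {
  long <- do.call(rbind, lapply(erps, function(e) {
    data.frame(subject = e$subject, condition = e$condition,
               channel = rep(rownames(e$data), each = ncol(e$data)),
               time_ms = rep(erp_times(e), times = nrow(e$data)),
               amplitude_uv = as.vector(t(e$data)),
               rate_hz = e$rate, epoch_start_ms = e$epoch_start,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_erp_csv
#' @export
read_erp_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(long[, c("subject", "condition")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- long[long$subject == keys$subject[i] & long$condition == keys$condition[i], ]
    ch <- unique(d$channel)
    tm <- sort(unique(d$time_ms))
    M <- matrix(NA_real_, length(ch), length(tm), dimnames = list(ch, NULL))
    M[cbind(match(d$channel, ch), match(d$time_ms, tm))] <- d$amplitude_uv
    subject_erp(keys$subject[i], keys$condition[i], M,
                rate = d$rate_hz[1], epoch_start = d$epoch_start_ms[1])
  })
}
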