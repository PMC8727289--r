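#' Encode binary methylation patterns as -1/+1 vectors
#'
#' Unmethylated (0) maps to -1 and methylated (1) to +1, matching the
#' hyperbolic-tangent activation range of the autoencoder; order is
#' preserved and decoding by sign is the identity on valid patterns.
#'
#' @param patterns character vector of strings over \{0,1\}
#' @param n region CpG count
#' @return numeric matrix in \{-1, +1\}, one row per pattern
#' @export
encode_reads <- function(patterns, n) {
  2 * pattern_bits(patterns, n) - 1
}

#' K-means clustering of training reads
#'
#' Partitions the encoded (-1/+1) training reads of one region into `k`
#' epiallele clusters (default 5), intended to separate reads from distinct
#' blood cell types before per-cluster autoencoder training. Reads are
#' count-weighted (each pattern contributes its multiplicity); when fewer
#' than `k` distinct patterns exist, `k` is reduced with a warning. Uses 10
#' random restarts and is deterministic under a fixed seed.
#'
#' @param reads pattern data frame of pooled control training reads for one
#'   region
#' @param region the `amplicon_region`
#' @param k number of clusters (default 5); `k = 1` disables clustering
#' @param seed integer seed
#' @return object of class `cluster_model` with `centroids` (k x n_cpgs)
#' @export
fit_clusters <- function(reads, region, k = 5L, seed = 1L) {
  if (nrow(reads) == 0L) stop("no training reads for clustering in region '",
                              region$region_id, "'")
  enc <- encode_reads(reads$pattern, n_cpgs(region))
  n_distinct <- nrow(unique(enc))
  if (n_distinct < k) {
    warning("only ", n_distinct, " distinct patterns in region '",
            region$region_id, "'; reducing k from ", k, " to ", n_distinct)
    k <- n_distinct
  }
  if (k == 1L) {
    w <- reads$count / sum(reads$count)
    centroids <- matrix(colSums(enc * w), nrow = 1L)
  } else {
    expanded <- enc[rep(seq_len(nrow(enc)), reads$count), , drop = FALSE]
    km <- local_seed(seed,
                     stats::kmeans(expanded, centers = k, nstart = 10L,
                                   iter.max = 100L))
    centroids <- km$centers
  }
  structure(list(region_id = region$region_id, k = k,
                 centroids = unname(centroids), seed = seed),
            class = "cluster_model")
}

#' Assign encoded reads to their nearest centroid
#'
#' Euclidean nearest-centroid assignment; ties go to the lowest cluster id.
#'
#' @param enc encoded read matrix (rows = reads, -1/+1 entries)
#' @param model a `cluster_model`
#' @return integer vector of cluster ids in 1..k
#' @export
assign_cluster <- function(enc, model) {
  cn <- rowSums(model$centroids^2)
  # squared distance = |x|^2 - 2 x.c + |c|^2; |x|^2 constant per row
  d <- sweep(-2 * enc %*% t(model$centroids), 2L, cn, `+`)
  max.col(-d, ties.method = "first")
}

# Glorot-uniform initialization of one weight matrix
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

ae_forward <- function(p, X) {
  A1 <- tanh(sweep(X %*% p$W1, 2L, p$b1, `+`))
  A2 <- tanh(sweep(A1 %*% p$W2, 2L, p$b2, `+`))
  A3 <- tanh(sweep(A2 %*% p$W3, 2L, p$b3, `+`))
  A4 <- tanh(sweep(A3 %*% p$W4, 2L, p$b4, `+`))
  list(A1 = A1, A2 = A2, A3 = A3, A4 = A4)
}

#' Per-read reconstruction loss of an autoencoder
#'
#' Mean squared error between each encoded read and its reconstruction.
#'
#' @param model an `ae_region_model` (one cluster's autoencoder)
#' @param enc encoded read matrix
#' @return numeric vector of per-read losses
#' @export
ae_read_loss <- function(model, enc) {
  rowMeans((ae_forward(model$params, enc)$A4 - enc)^2)
}

#' Train one autoencoder on a cluster's reads
#'
#' Feed-forward autoencoder with hidden widths 8-3-8 (encoder, latent,
#' decoder), input and output width equal to the region's CpG count, and
#' hyperbolic-tangent activations on all hidden and output layers. Trained
#' to minimize the count-weighted mean squared reconstruction error by
#' full-batch gradient descent with adaptive-moment (Adam) updates; training
#' stops early when the loss plateaus. The abnormal-read threshold is the
#' 99th linear-interpolation percentile of the training reads' losses
#' (count-weighted: each read, not each distinct pattern, counts once).
#'
#' @param reads pattern data frame (one region, one cluster)
#' @param region the `amplicon_region`
#' @param epochs maximum training epochs (default 2000)
#' @param lr Adam learning rate (default 0.01)
#' @param threshold_percentile percentile for the loss threshold (default 99)
#' @param seed integer seed; training is deterministic under a fixed seed
#' @return object of class `ae_region_model` with fields `params` (weights),
#'   `loss_threshold`, `final_loss`
#' @export
train_autoencoder <- function(reads, region, epochs = 2000L, lr = 0.01,
                              threshold_percentile = 99, seed = 1L) {
  stopifnot(nrow(reads) >= 1L)
  n <- n_cpgs(region)
  X <- encode_reads(reads$pattern, n)
  w <- reads$count / sum(reads$count)

  widths <- c(n, 8L, 3L, 8L, n)
  p <- local_seed(seed, list(
    W1 = glorot(widths[1], widths[2]), b1 = numeric(widths[2]),
    W2 = glorot(widths[2], widths[3]), b2 = numeric(widths[3]),
    W3 = glorot(widths[3], widths[4]), b3 = numeric(widths[4]),
    W4 = glorot(widths[4], widths[5]), b4 = numeric(widths[5])))

  m <- lapply(p, function(x) x * 0)
  v <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- Inf; stale <- 0L
  for (t in seq_len(epochs)) {
    f <- ae_forward(p, X)
    err <- f$A4 - X
    loss <- sum(w * rowMeans(err^2))
    if (!is.finite(loss))
      stop("autoencoder training diverged (non-finite loss) in region '",
           region$region_id, "' at epoch ", t)
    # plateau-based early stop
    if (loss < best - 1e-9) { best <- loss; stale <- 0L }
    else { stale <- stale + 1L; if (stale >= 50L) break }

    dA4 <- 2 * err * (w / n)                    # d loss / d A4
    dZ4 <- dA4 * (1 - f$A4^2)
    dZ3 <- (dZ4 %*% t(p$W4)) * (1 - f$A3^2)
    dZ2 <- (dZ3 %*% t(p$W3)) * (1 - f$A2^2)
    dZ1 <- (dZ2 %*% t(p$W2)) * (1 - f$A1^2)
    g <- list(W1 = t(X) %*% dZ1,   b1 = colSums(dZ1),
              W2 = t(f$A1) %*% dZ2, b2 = colSums(dZ2),
              W3 = t(f$A2) %*% dZ3, b3 = colSums(dZ3),
              W4 = t(f$A3) %*% dZ4, b4 = colSums(dZ4))
    for (k in names(p)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
      mh <- m[[k]] / (1 - b1^t)
      vh <- v[[k]] / (1 - b2^t)
      p[[k]] <- p[[k]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  model <- structure(list(region_id = region$region_id, n_cpgs = n,
                          params = p, seed = seed, epochs_run = t),
                     class = "ae_region_model")
  losses <- ae_read_loss(model, X)
  model$final_loss <- sum(w * losses)
  model$loss_threshold <- weighted_percentile(losses, reads$count,
                                              threshold_percentile)
  model
}

# linear-interpolation percentile of values replicated by integer weights
weighted_percentile <- function(values, weights, percentile) {
  unname(stats::quantile(rep(values, weights), probs = percentile / 100,
                         type = 7, names = FALSE))
}

#' Train the panel-wide autoencoder anomaly model
#'
#' For each panel region, pooled control training reads are optionally
#' partitioned into `k` epiallele clusters by K-means (`k = 5` default; any
#' `k <= 1` disables clustering) and one autoencoder is trained per cluster.
#' Each autoencoder carries its own 99th-percentile loss threshold; a read
#' is abnormal when its reconstruction loss under its assigned cluster's
#' autoencoder exceeds that threshold.
#'
#' @param control_reads pattern data frame of pooled control training samples
#' @param panel a `region_panel`
#' @param k number of clusters per region (default 5; 1 = no clustering)
#' @param epochs,lr,threshold_percentile forwarded to [train_autoencoder()]
#' @param seed integer seed
#' @return object of class `ae_model`
#' @export
train_ae_model <- function(control_reads, panel = default_panel(), k = 5L,
                           epochs = 2000L, lr = 0.01,
                           threshold_percentile = 99, seed = 1L) {
  k <- max(1L, as.integer(k))
  models <- lapply(panel$regions, function(r) {
    rr <- control_reads[control_reads$region_id == r$region_id, ,
                        drop = FALSE]
    if (nrow(rr) == 0L)
      stop("no training reads for region '", r$region_id, "'")
    cm <- if (k > 1L) fit_clusters(rr, r, k = k, seed = seed) else NULL
    assign <- if (is.null(cm)) rep(1L, nrow(rr))
      else assign_cluster(encode_reads(rr$pattern, n_cpgs(r)), cm)
    kk <- if (is.null(cm)) 1L else cm$k
    aes <- lapply(seq_len(kk), function(ci) {
      sub <- rr[assign == ci, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)  # empty cluster: dropped
      train_autoencoder(sub, r, epochs = epochs, lr = lr,
                        threshold_percentile = threshold_percentile,
                        seed = seed + ci)
    })
    if (any(vapply(aes, is.null, logical(1))))
      warning("empty cluster(s) dropped in region '", r$region_id, "'")
    list(region = r, cluster_model = cm, aes = aes)
  })
  structure(list(regions = models, panel = panel, k = k, seed = seed,
                 params = list(epochs = epochs, lr = lr,
                               threshold_percentile = threshold_percentile)),
            class = "ae_model")
}

#' @export
classify_region_reads.ae_model <- function(model, region_id, reads) {
  rm_ <- model$regions[[region_id]]
  if (is.null(rm_)) stop("no autoencoder model for region '", region_id, "'")
  enc <- encode_reads(reads$pattern, n_cpgs(rm_$region))
  assign <- if (is.null(rm_$cluster_model)) rep(1L, nrow(reads))
    else assign_cluster(enc, rm_$cluster_model)
  out <- character(nrow(reads))
  for (ci in unique(assign)) {
    ae <- rm_$aes[[ci]]
    idx <- assign == ci
    if (is.null(ae)) {
      # reads routed to a dropped (empty) training cluster: use the nearest
      # non-empty cluster's autoencoder
      alive <- which(!vapply(rm_$aes, is.null, logical(1)))
      ae <- rm_$aes[[alive[1]]]
    }
    loss <- ae_read_loss(ae, enc[idx, , drop = FALSE])
    out[idx] <- ifelse(loss > ae$loss_threshold, "abnormal", "normal")
  }
  out
}
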