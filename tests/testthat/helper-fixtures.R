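# Shared helpers: greedy ground-truth/detection matching and a brute-force
# per-pixel oracle for the threshold/ratio colocalization rule.

match_spots <- function(truth, det, tol_px = 20) {
  used <- rep(FALSE, nrow(det))
  hit <- logical(nrow(truth))
  pair <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (nrow(det) == 0) break
    d <- sqrt((det$y - truth$y[i])^2 + (det$x - truth$x[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_px) {
      hit[i] <- TRUE; used[j] <- TRUE; pair[i] <- j
    }
  }
  list(recall = mean(hit), precision = sum(used) / max(1, nrow(det)),
       hit = hit, pair = pair)
}

# literal per-pixel evaluation of the colocalization rule
brute_coloc_count <- function(a, b, ratio, ta, tb) {
  n <- 0L
  for (i in seq_along(a)) {
    if (a[i] < ta || b[i] < tb) next
    hi <- max(a[i], b[i]); lo <- min(a[i], b[i])
    if (hi == 0 || 100 * lo / hi >= ratio) n <- n + 1L
  }
  n
}

run_zymo_scene <- function(sc) {
  ss <- detect_digestion(sc$stack, mode = sc$truth$mode)
  ss <- assign_spots(ss, sc$cell_labels)
  classify_active(ss, get_channel(sc$stack, "actin"),
                  get_channel(sc$stack, "cortactin"))
}
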