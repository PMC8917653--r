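# shared in-code fixtures for the suite

# small cohort for fast end-to-end style tests
small_config <- function(seed = 1L, ...) {
  simulation_config(
    group_sizes = c("lean-BD" = 6, obese = 6, lipodystrophy = 10,
                    BD = 40),
    layer_specs = list(
      layer_spec("metabolites", "abundance", n_features = 60,
                 n_planted = 5, effect_size = 1.5),
      layer_spec("rna", "counts", n_features = 60, n_planted = 5,
                 effect_size = 1.5)),
    n_modules = 0, seed = seed, ...)
}

# samples x features block-structured data with known modules
block_data <- function(n = 100, n_modules = 4, module_size = 30,
                       within_r = 0.6, n_noise = 80, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n_modules * n), ncol = n_modules)
  blocks <- lapply(seq_len(n_modules), function(k)
    sqrt(within_r) * matrix(rep(f[, k], module_size), ncol = module_size) +
      sqrt(1 - within_r) * matrix(rnorm(n * module_size),
                                  ncol = module_size))
  x <- cbind(do.call(cbind, blocks),
             matrix(rnorm(n * n_noise), ncol = n_noise))
  colnames(x) <- paste0("met", seq_len(ncol(x)))
  truth <- c(rep(paste0("T", seq_len(n_modules)), each = module_size),
             rep("none", n_noise))
  list(x = x, truth = stats::setNames(truth, colnames(x)), factors = f)
}

# independent brute-force per-base oracle for peak merging
oracle_merge_peaks <- function(intervals, min_support, genome_len = 10000) {
  out <- NULL
  for (cc in unique(intervals$chrom)) {
    d <- intervals[intervals$chrom == cc, ]
    support <- integer(genome_len)
    for (s in unique(d$sample_id)) {
      covered <- logical(genome_len)
      ds <- d[d$sample_id == s, ]
      for (i in seq_len(nrow(ds)))
        covered[(ds$start[i] + 1):ds$end[i]] <- TRUE
      support <- support + covered
    }
    keep <- support >= min_support
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values)
    if (length(hit) > 0)
      out <- rbind(out, data.frame(chrom = cc, start = starts[hit] - 1L,
                                   end = ends[hit]))
  }
  if (is.null(out)) data.frame(chrom = character(0), start = integer(0),
                               end = integer(0)) else out
}

# lipid panel with planted signature species over the three study groups
make_lipid_panel <- function(seed, n_sig = 9, n_null = 50, shift = 3) {
  set.seed(seed)
  groups <- rep(c("lean-BD", "obese", "lipodystrophy", "BD"),
                times = c(8, 8, 10, 20))
  n <- length(groups)
  panel <- matrix(rnorm((n_sig + n_null) * n), n_sig + n_null, n,
                  dimnames = list(
                    c(paste0("sig", seq_len(n_sig)),
                      paste0("null", seq_len(n_null))),
                    paste0("s", seq_len(n))))
  case <- groups %in% c("obese", "lipodystrophy")
  panel[seq_len(n_sig), case] <- panel[seq_len(n_sig), case] + shift
  list(panel = panel, groups = groups,
       signature = paste0("sig", seq_len(n_sig)))
}

# direct-formula bicor oracle (independent of the vectorised code path)
oracle_bicor <- function(x, y) {
  bw <- function(v) {
    u <- (v - median(v)) / (9 * median(abs(v - median(v))))
    (v - median(v)) * (1 - u^2)^2 * (abs(u) < 1)
  }
  a <- bw(x); b <- bw(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
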