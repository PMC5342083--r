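# Small internal helpers shared across modules.

# FNV-1a 32-bit hash of a string, returned as 8 hex digits. Used only to
# stamp output files with a short fingerprint of the configuration.
.fnv1a <- function(s) {
    bytes <- as.integer(charToRaw(s))
    h <- 2166136261
    for (b in bytes) {
        # xor touches only the low byte; keep arithmetic in doubles < 2^41
        h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
        lo <- h %% 65536
        hi <- h %/% 65536
        h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
    }
    paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# Canonical one-line echo of a config, used in log headers and hashing.
.configString <- function(config) {
    paste(sprintf("fdr_threshold=%g", config@fdrThreshold),
          sprintf("abs_fc_threshold=%g", config@absFcThreshold),
          sprintf("window_halfwidth=%g", config@windowHalfwidth),
          sprintf("kmeans_k=%d", config@kmeansK),
          sprintf("merge_corr_threshold=%g", config@mergeCorrThreshold),
          sprintf("age_grid_step=%g", config@ageGridStep),
          sprintf("random_seed=%d", config@randomSeed),
          sprintf("weighting_enabled=%s", config@weightingEnabled),
          sprintf("fc_mode=%s", config@fcMode),
          sprintf("kmeans_restarts=%d", config@kmeansRestarts),
          sep = " ")
}

# Format numerics with enough digits to round-trip through decimal text.
.fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

.fmtMat <- function(m) {
    out <- matrix(.fmtNum(m), nrow = nrow(m), dimnames = dimnames(m))
    as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}
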