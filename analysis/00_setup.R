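# Shared configuration for the analysis drivers.
#
# The synthetic study mirrors the design of the real one: a whey protein
# concentrate (WPC) benchmark ion table, an enzyme-only blank, and 18 protein
# digests (the WPC digest itself among them) measured in triplicate on the
# LC-MS side, plus a 7-variable biological read-out panel over the 18 digests
# and the blank. Per-source overlap fractions with the benchmark span the
# range reported for real digests (roughly 8% to 83%), with
# alternative-source digests at the high end, the whey digests highest, and
# plant digests lower.

library(pepdigest)

OUT_DIR <- "results"
DATA_DIR <- file.path(OUT_DIR, "data")
BENCH_FILE <- "WPC_benchmark.csv"

SEED <- 20201217L

SOURCES <- data.frame(
  source_id = c("WPC", "AWPC", "Egg", "Soy", "NPP", "NWP", "BP", "CH",
                "LM", "LMC2", "TPP1", "TPP2", "QM", "QrtoE", "Wheat",
                "Corn", "YE", "Yesol"),
  overlap = c(0.95, 0.826, 0.30, 0.25, 0.20, 0.15, 0.28, 0.22,
              0.60, 0.65, 0.18, 0.16, 0.70, 0.68, 0.10,
              0.078, 0.62, 0.35),
  n_ions = c(450, 420, 300, 310, 280, 260, 320, 290,
             240, 230, 300, 310, 220, 225, 330,
             340, 235, 280),
  stringsAsFactors = FALSE)

N_REPLICATES <- 3L
N_BENCHMARK_IONS <- 500L
N_BLANK_IONS <- 120L

base_config <- function(source_row = NULL) {
  if (is.null(source_row)) {
    ion_sim_config(seed = SEED, n_benchmark_ions = N_BENCHMARK_IONS,
                   n_blank_ions = N_BLANK_IONS)
  } else {
    ion_sim_config(seed = SEED, n_benchmark_ions = N_BENCHMARK_IONS,
                   n_blank_ions = N_BLANK_IONS,
                   n_digest_ions = source_row$n_ions,
                   overlap_fraction = source_row$overlap)
  }
}

read_benchmark <- function() {
  read_ion_table(file.path(DATA_DIR, BENCH_FILE), "WPC", "benchmark",
                 columns = ion_column_map(ion_id = "ion_id"))
}

read_blank <- function() {
  read_ion_table(file.path(DATA_DIR, "Blank_R1.csv"), "Blank", "R1",
                 columns = ion_column_map(ion_id = "ion_id"))
}

read_digests <- function() {
  digests <- list()
  for (i in seq_len(nrow(SOURCES))) {
    for (r in seq_len(N_REPLICATES)) {
      sid <- SOURCES$source_id[i]
      digests[[length(digests) + 1L]] <- read_ion_table(
        file.path(DATA_DIR, sprintf("%s_R%d.csv", sid, r)), sid,
        paste0("R", r), columns = ion_column_map(ion_id = "ion_id"))
    }
  }
  digests
}

# biological panel: six behavioural groups over blank + 18 digests, echoing
# the kind of partition the assays produce (a large average group with the
# benchmark, a blank-like high-ZO-1 group, a high-alkaline-phosphatase plant
# group, an immune-activating egg group, a high-NO insect group, and a
# high-TGF-beta group)
BIO_SOURCES <- c("Blank", SOURCES$source_id)
BIO_ASSIGNMENT <- c(2, 1, 1, 4, 3, 1, 3, 2, 1, 5, 1, 1, 6, 1, 1, 3, 3, 3, 3)
BIO_MEANS <- {
  m <- matrix(100, 6, 7)
  m[2, 2] <- 112   # blank-like: high ZO-1
  m[3, 4] <- 112   # high alkaline phosphatase
  m[4, 5] <- 112   # IL-6 induction
  m[5, 7] <- 112   # high NO
  m[6, 6] <- 112   # high TGF-beta
  m
}

bio_config <- function() {
  bio_sim_config(seed = SEED, source_ids = BIO_SOURCES,
                 n_clusters = 6L, assignment = BIO_ASSIGNMENT,
                 cluster_means = BIO_MEANS, noise_sd = 1,
                 n_replicates = N_REPLICATES, outlier_rate = 0.05)
}
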