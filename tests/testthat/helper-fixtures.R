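# Shared fixtures, built in code.

# tensor of noise-free trajectories from a single known operator,
# identical design for every line unless x1 varies
make_planted_tensor <- function(A, x1_list, days = unlist(make_block_days())) {
  p <- nrow(A)
  k <- length(x1_list)
  all_days <- seq(min(days), max(days))
  meas <- match(days, all_days)
  vals <- array(NA_real_, c(k, p, length(days)))
  for (i in seq_len(k)) {
    x <- x1_list[[i]]
    traj <- matrix(NA_real_, p, length(all_days))
    traj[, 1] <- x
    for (d in seq_along(all_days)[-1]) {
      x <- as.numeric(A %*% x)
      traj[, d] <- x
    }
    vals[i, , ] <- traj[, meas]
  }
  trait_tensor(vals, paste0("L", seq_len(k)), paste0("t", seq_len(p)), days)
}

# small long-format phenotype tibble for I/O tests
make_long_pheno <- function(lines = c("A", "B"), traits = c("x", "y"),
                            days = c(15, 16, 17, 20, 21)) {
  g <- expand.grid(line = lines, trait = traits, day = days,
                   stringsAsFactors = FALSE)
  g$value <- seq_len(nrow(g)) / 10
  tibble::as_tibble(g)
}

# minimal VCF text with n biallelic records and optionally one triallelic
write_tiny_vcf <- function(path, triallelic = FALSE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL1\tL2\tL3")
  recs <- c(
    "1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\ts2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0",
    "1\t300\ts3\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1",
    "1\t400\ts4\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
    "1\t500\ts5\tA\tC\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0")
  if (triallelic)
    recs[3] <- "1\t300\ts3\tG\tA,C\t.\tPASS\t.\tGT\t1/1\t0/0\t0/2"
  writeLines(c(hdr, recs), path)
  path
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
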