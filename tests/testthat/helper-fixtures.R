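# Fixtures built in code: tiny models and independent oracles.

chain_model <- function(uptake = 10) {
  mets <- dplyr::bind_rows(
    metabolite("A_e", formula = "C6H12O6"),
    metabolite("A_c", formula = "C6H12O6")
  )
  rxns <- dplyr::bind_rows(
    reaction("EX_A", c(A_e = -1), -uptake, 1000, category = "exchange"),
    reaction("T_A", c(A_e = -1, A_c = 1), 0, 1000),
    reaction("BIOMASS", c(A_c = -1), 0, 1000, category = "biomass")
  )
  metabolic_model("chain", mets, rxns)
}

# Branched toy network with 2:1 substrate coupling into biomass.
branch_model <- function(uptake_a = 10, uptake_b = 10) {
  mets <- dplyr::bind_rows(
    metabolite("A_e", formula = "C6H12O6"), metabolite("A_c", formula = "C6H12O6"),
    metabolite("B_e", formula = "C5H10O5"), metabolite("B_c", formula = "C5H10O5")
  )
  rxns <- dplyr::bind_rows(
    reaction("EX_A", c(A_e = -1), -uptake_a, 1000, category = "exchange"),
    reaction("EX_B", c(B_e = -1), -uptake_b, 1000, category = "exchange"),
    reaction("T_A", c(A_e = -1, A_c = 1), 0, 1000),
    reaction("T_B", c(B_e = -1, B_c = 1), 0, 1000),
    reaction("BIOMASS", c(A_c = -2, B_c = -1), 0, 1000, category = "biomass")
  )
  metabolic_model("branch", mets, rxns)
}

# Independent LP reference: scipy HiGHS, driven through the bundled script.
# Used only as an oracle; never as the implementation.
oracle_lp_batch <- function(instances) {
  script <- system.file("oracle", "lp_oracle.py", package = "fluxprint")
  stopifnot(nzchar(script))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  payload <- list(instances = lapply(instances, function(i) {
    list(S = i$S, lb = i$lb, ub = i$ub, obj = i$obj)
  }))
  jsonlite::write_json(payload, fin, digits = NA, matrix = "rowmajor", auto_unbox = FALSE)
  status <- system2("python", c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  stopifnot(file.exists(fout))
  jsonlite::read_json(fout, simplifyVector = FALSE)$results
}

oracle_lp <- function(S, lb, ub, obj) {
  oracle_lp_batch(list(list(S = S, lb = lb, ub = ub, obj = obj)))[[1]]
}

# Secondary oracle in pure R (boot::simplex); returns NULL when the
# reference solver itself fails to converge on an instance.
oracle_lp_boot <- function(S, lb, ub, obj) {
  n <- length(obj)
  b3 <- as.numeric(-S %*% lb)
  A3 <- S
  qrT <- qr(t(A3))
  keep <- qrT$pivot[seq_len(qrT$rank)]
  A3 <- A3[keep, , drop = FALSE]
  b3 <- b3[keep]
  fl <- b3 < 0
  A3[fl, ] <- -A3[fl, , drop = FALSE]
  b3[fl] <- -b3[fl]
  res <- tryCatch(
    boot::simplex(
      a = obj, A1 = diag(1, n), b1 = ub - lb, A3 = A3, b3 = b3,
      maxi = TRUE, n.iter = 5000
    ),
    error = function(e) NULL
  )
  if (is.null(res) || res$solved == 0) return(NULL)
  if (res$solved == -1) return(list(status = "infeasible", objective = NULL))
  list(status = "optimal", objective = sum(obj * (as.numeric(res$soln) + lb)))
}

# Brute-force average-linkage agglomeration (independent of stats::hclust):
# returns merge heights in order.
brute_force_average_linkage <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  avg_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- avg_dist(clusters[[i]], clusters[[j]])
          if (h < best_h - 1e-12) {
            best_h <- h
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}
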