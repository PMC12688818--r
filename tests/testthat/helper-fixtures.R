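# In-code fixtures shared across test files.

# A minimal analysis-ready case-report tibble: one row per report with the
# columns the counting, screening and TTO stages consume.
make_reports <- function(events, is_target, sex = NULL,
                         event_dt = NULL, start_dt = NULL) {
  n <- length(events)
  tibble::tibble(
    primaryid = seq_len(n) * 10L + 1L,
    caseid = seq_len(n),
    fda_dt = "20240101",
    sex = sex %||% rep(NA_character_, n),
    age_years = NA_real_, weight_kg = NA_real_,
    reporter_code = NA_character_, country = "US",
    event_dt = event_dt %||% rep("", n),
    start_dt = start_dt %||% rep("", n),
    outcomes = rep(list(character(0)), n),
    drugs = rep(list(tibble::tibble(drug_seq = 1L, role_cod = "PS",
                                    drugname = "X", prod_ai = "X")), n),
    events = events,
    is_target = is_target
  )
}

# Write a tiny hand-constructed set of FAERS-dialect quarterly files and
# return the directory. Three reports: 101 (target PS + concomitant, two
# events), 102 (non-target, one event, blank sex), 103 (target drug in
# concomitant role only).
write_tiny_faers <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  w <- function(name, lines) writeLines(lines, file.path(dir, name))
  w("DEMO24Q1.txt", c(
    "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$occp_cod$reporter_country",
    "101$11$20240110$20240105$F$34$YR$62$KG$MD$US",
    "102$12$20240111$$$45$YR$$$PH$FR",
    "103$13$20240112$202401$M$$$80$KG$$JP"
  ))
  w("DRUG24Q1.txt", c(
    "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai",
    "101$11$1$PS$NAROPIN 0.2% INJ$ROPIVACAINE",
    "101$11$2$C$MIDAZOLAM$MIDAZOLAM",
    "102$12$1$PS$LIDOCAINE$LIDOCAINE",
    "103$13$1$PS$PROPOFOL$PROPOFOL",
    "103$13$2$C$ROPIVACAINE$ROPIVACAINE"
  ))
  w("REAC24Q1.txt", c(
    "primaryid$caseid$pt",
    "101$11$Hypotension",
    "101$11$Bradycardia",
    "102$12$Nausea",
    "103$13$Seizure"
  ))
  w("THER24Q1.txt", c(
    "primaryid$caseid$dsg_drug_seq$start_dt$end_dt",
    "101$11$1$20240103$",
    "102$12$1$20240101$",
    "103$13$1$20240102$"
  ))
  w("OUTC24Q1.txt", c(
    "primaryid$caseid$outc_cod",
    "101$11$HO",
    "102$12$OT"
  ))
  w("RPSR24Q1.txt", c(
    "primaryid$caseid$rpsr_cod",
    "101$11$HP", "102$12$HP", "103$13$HP"
  ))
  dir
}

# Join a generator's raw quarterly tables (duplicates included) into the
# report-version form, bypassing file I/O.
join_reports_for_test <- function(gen) {
  pharmsig:::join_faers_tables(gen$tables$demo, gen$tables$drug,
                               gen$tables$reac, gen$tables$ther,
                               gen$tables$outc)
}

# Independent closed-form evaluation of the four statistics for one 2x2
# table, written long-hand so package code and oracle share nothing.
oracle_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2_yates <- n * (abs(a * d - b * c) - n / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  chi2_raw <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2.0 * (a + 0.5)^(-1.5)
  list(ror = ror, ror_lo = exp(log(ror) - 1.96 * se),
       ror_hi = exp(log(ror) + 1.96 * se),
       prr = prr, chi2_yates = chi2_yates, chi2_raw = chi2_raw,
       e = e, ic = ic, ic025 = ic025)
}
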