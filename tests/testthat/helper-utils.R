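`%||%` <- function(a, b) if (is.null(b)) a else if (is.null(a)) b else a

# minimal scan_result stand-in for driving trace_occurrence() with raw
# score tables (bypassing profile construction)
fake_scan_result <- function(tcode, m, sigma_table, tpairs, qpairs,
                             tau_tables, params, sj) {
  prof <- build_profile(query_input(strrep("N", m)))
  structure(list(target_id = "t", n = length(tcode), m = m,
                 score_trace = sj, params = params, profile = prof,
                 seq_scores = FALSE, target_code = tcode,
                 sigma_table = sigma_table, tpairs = tpairs,
                 qpairs = qpairs, tau_tables = tau_tables),
            class = "scan_result")
}
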