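# Classed conditions so callers can distinguish failure modes programmatically.
# Every error carries the umbrella class "crt_error" plus a specific subclass.

crt_abort <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "crt_error"), call = call))
}

abort_duplicate_gene <- function(msg) crt_abort("crt_duplicate_gene_error", msg)
abort_parse          <- function(msg) crt_abort("crt_parse_error", msg)
abort_label          <- function(msg) crt_abort("crt_label_error", msg)
abort_alignment      <- function(msg) crt_abort("crt_alignment_error", msg)
abort_spec           <- function(msg) crt_abort("crt_spec_error", msg)
abort_stat           <- function(msg) crt_abort("crt_stat_error", msg)
abort_selection      <- function(msg) crt_abort("crt_selection_error", msg)
abort_algorithm      <- function(msg) crt_abort("crt_algorithm_error", msg)
abort_feature        <- function(msg) crt_abort("crt_feature_error", msg)
abort_train          <- function(msg) crt_abort("crt_train_error", msg)
abort_fold           <- function(msg) crt_abort("crt_fold_error", msg)
abort_match          <- function(msg) crt_abort("crt_match_error", msg)
abort_profile        <- function(msg) crt_abort("crt_profile_error", msg)
abort_rebuild        <- function(msg) crt_abort("crt_rebuild_error", msg)
abort_eval           <- function(msg) crt_abort("crt_eval_error", msg)
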