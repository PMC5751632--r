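#' @importFrom data.table := fread fwrite as.data.table rbindlist melt dcast
#'   uniqueN setorder data.table
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "timestamp", "channel", "value", "label", "window_start", "stat",
  "feature", "time_of_day", "nch", "state", "node_id"))
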