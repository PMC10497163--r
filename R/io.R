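#' Read boards from a JSON Lines file
#'
#' One board per line in the `board/v1` schema:
#' `{"schema":"board/v1","rule":"rectangle","board_id":"rectangle-0001",`
#' `"grid":[[0,1,...],...]}` where `grid` is a list of 7 rows (row 1 = top),
#' each a list of 7 values, 1 = red and 0 = blue.  Malformed lines (wrong
#' shape, non-binary values) are rejected with the offending line number.
#'
#' @param path file path.
#' @return list of boards.
#' @export
read_boards <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyMatrix = TRUE),
                    error = function(e) {
                      stop(sprintf("line %d: invalid JSON (%s)", i,
                                   conditionMessage(e)))
                    })
    grid <- rec$grid
    if (is.null(grid)) stop(sprintf("line %d: missing grid", i))
    grid <- as.matrix(grid)
    if (!identical(dim(grid), c(7L, 7L))) {
      stop(sprintf("line %d: grid must be 7x7, got %dx%d", i,
                   nrow(grid), ncol(grid)))
    }
    if (!all(grid %in% c(0, 1))) {
      stop(sprintf("line %d: grid values must be 0 or 1", i))
    }
    # JSON rows are board rows; internal storage keeps [row, col] layout
    storage.mode(grid) <- "integer"
    new_board(grid, rule = rec$rule, board_id = rec$board_id)
  })
}

#' Write boards to a JSON Lines file
#'
#' Writes atomically (temporary file + rename) in the `board/v1` schema;
#' see [read_boards()].
#'
#' @param boards list of boards.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_boards <- function(boards, path) {
  lines <- vapply(seq_along(boards), function(i) {
    b <- boards[[i]]
    g <- as.matrix(b)
    rule <- attr(b, "rule")
    board_id <- attr(b, "board_id")
    if (is.null(board_id)) {
      board_id <- sprintf("%s-%04d", if (is.null(rule)) "board" else rule, i)
    }
    rec <- list(schema = "board/v1",
                rule = if (is.null(rule)) NA_character_ else rule,
                board_id = board_id,
                grid = unname(lapply(seq_len(nrow(g)), function(r)
                  as.integer(g[r, ]))))
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write episode traces to a JSON Lines file
#'
#' One episode per line: `{"schema":"trace/v1","terminal":...,`
#' `"blue_count":...,"steps":[{"observation":[...],"action":...,`
#' `"reward":...}, ...]}`.  Written atomically.
#'
#' @param episodes list of [run_episode()] results recorded with
#'   `record_trace = TRUE`.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_traces <- function(episodes, path) {
  lines <- vapply(episodes, function(ep) {
    if (is.null(ep$trace)) stop("episode has no recorded trace")
    jsonlite::toJSON(list(schema = "trace/v1", terminal = ep$done,
                          blue_count = ep$blue_count, steps = ep$trace),
                     auto_unbox = TRUE)
  }, character(1))
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a results table to CSV atomically
#'
#' @param results data.frame (e.g. from [run_condition()]).
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(results, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
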