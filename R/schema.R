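#' Event schema: types, roles and filler constraints
#'
#' An event schema declares which event types exist, which argument roles
#' each type accepts, which filler categories (entity types or event types)
#' each role admits, and how many fillers of each role an event may carry.
#' Every gold event of a conforming corpus, and every event the extractor
#' emits, must satisfy these constraints.
#'
#' @param entity_types character vector of entity type names.
#' @param event_types named list; one entry per event type, itself a named
#'   list mapping each role name to a list with elements `fillers`
#'   (character vector of admissible entity/event type names), `min` and
#'   `max` (integer filler counts for that role).
#' @return An object of class `event_schema`.
#' @examples
#' sch <- event_schema(
#'   entity_types = c("Gene"),
#'   event_types = list(
#'     Expression = list(Theme = list(fillers = "Gene", min = 1, max = 1))
#'   )
#' )
#' @export
event_schema <- function(entity_types, event_types) {
  stopifnot(is.character(entity_types), length(event_types) >= 1)
  if (is.null(names(event_types)) || any(names(event_types) == ""))
    stop("every event type must be named")
  event_types <- lapply(event_types, function(roles) {
    lapply(roles, function(r) {
      r$min <- as.integer(r$min %||% 0L)
      r$max <- as.integer(r$max %||% 1L)
      if (r$min < 0 || r$max < r$min) stop("invalid role min/max")
      r$fillers <- as.character(r$fillers)
      r
    })
  })
  structure(
    list(entity_types = as.character(entity_types),
         event_types = event_types),
    class = "event_schema"
  )
}

#' @export
print.event_schema <- function(x, ...) {
  cat("Event schema:", length(x$event_types), "event types,",
      length(x$entity_types), "entity types\n")
  for (et in names(x$event_types)) {
    roles <- x$event_types[[et]]
    cat("  ", et, ": ", paste(vapply(names(roles), function(rn) {
      r <- roles[[rn]]
      sprintf("%s[%d..%d]<-{%s}", rn, r$min, r$max,
              paste(r$fillers, collapse = ","))
    }, ""), collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Read an event schema from a YAML file
#'
#' The file must contain `entity_types` (sequence) and `event_types`
#' (mapping event type -> role -> {fillers, min, max}).
#'
#' @param path path to a YAML schema file.
#' @return An `event_schema`.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$entity_types) || is.null(y$event_types))
    stop("schema YAML must define entity_types and event_types")
  event_schema(unlist(y$entity_types), y$event_types)
}

#' Write an event schema to YAML
#' @param schema an `event_schema`.
#' @param path output file path.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(list(entity_types = schema$entity_types,
                        event_types = schema$event_types), path)
}

#' Built-in toy schema
#'
#' A minimal schema mirroring the canonical nested-regulation motif of
#' BioNLP-style corpora: a flat `Expression` event over `Gene` entities and
#' a `Regulation` event whose Theme/Cause may be an entity or another
#' event, so nested structures arise.
#'
#' @return An `event_schema`.
#' @export
toy_schema <- function() {
  event_schema(
    entity_types = c("Gene", "Disease"),
    event_types = list(
      Expression = list(
        Theme = list(fillers = "Gene", min = 1, max = 1)
      ),
      Regulation = list(
        Theme = list(fillers = c("Gene", "Disease", "Expression", "Regulation"),
                     min = 1, max = 1),
        Cause = list(fillers = c("Gene", "Expression", "Regulation"),
                     min = 0, max = 1)
      )
    )
  )
}

schema_roles <- function(schema)
  sort(unique(unlist(lapply(schema$event_types, names))))

schema_event_types <- function(schema) names(schema$event_types)

# Is `role` with a filler of category `filler_type` admissible for an event
# of type `event_type`?
schema_allows <- function(schema, event_type, role, filler_type = NULL) {
  roles <- schema$event_types[[event_type]]
  if (is.null(roles) || is.null(roles[[role]])) return(FALSE)
  if (is.null(filler_type)) return(TRUE)
  filler_type %in% roles[[role]]$fillers
}

# Check one argument multiset {role -> count} against min/max constraints.
schema_counts_ok <- function(schema, event_type, roles_used) {
  decl <- schema$event_types[[event_type]]
  if (is.null(decl)) return(FALSE)
  cnt <- table(factor(roles_used, levels = names(decl)))
  for (rn in names(decl)) {
    k <- as.integer(cnt[[rn]])
    if (k < decl[[rn]]$min || k > decl[[rn]]$max) return(FALSE)
  }
  # roles not declared for this type are forbidden
  all(roles_used %in% names(decl))
}

#' Validate a document's events against a schema
#'
#' Checks, independently of the extraction pipeline, that every event's
#' roles and filler categories are admissible, the per-role counts respect
#' the declared min/max, and the event graph is acyclic.
#'
#' @param doc an `so_document`.
#' @param schema an `event_schema`.
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_events <- function(doc, schema) {
  errs <- character(0)
  ev_type <- function(eid) {
    ev <- doc$events[[eid]]
    doc$triggers$type[match(ev$trigger_id, doc$triggers$id)]
  }
  for (eid in names(doc$events)) {
    ev <- doc$events[[eid]]
    et <- ev_type(eid)
    if (!et %in% names(schema$event_types)) {
      errs <- c(errs, sprintf("%s: unknown event type %s", eid, et))
      next
    }
    roles <- ev$args$role
    if (!schema_counts_ok(schema, et, roles))
      errs <- c(errs, sprintf("%s: role counts violate schema", eid))
    for (k in seq_len(nrow(ev$args))) {
      fid <- ev$args$filler_id[k]
      ftype <- if (ev$args$filler_kind[k] == "entity")
        doc$entities$type[match(fid, doc$entities$id)]
      else ev_type(fid)
      if (!schema_allows(schema, et, ev$args$role[k], ftype))
        errs <- c(errs, sprintf("%s: role %s does not admit filler type %s",
                                eid, ev$args$role[k], ftype))
    }
  }
  if (length(event_graph_cycle(doc$events)) > 0)
    errs <- c(errs, "event graph contains a cycle")
  errs
}

# Returns ids on a cycle of the event->sub-event graph, or character(0).
event_graph_cycle <- function(events) {
  ids <- names(events)
  adj <- lapply(events, function(ev) {
    k <- ev$args$filler_kind == "event"
    ev$args$filler_id[k]
  })
  state <- setNames(rep(0L, length(ids)), ids)  # 0 unseen, 1 in stack, 2 done
  found <- character(0)
  visit <- function(id) {
    if (length(found) > 0 || !id %in% ids) return()
    if (state[[id]] == 1L) { found <<- id; return() }
    if (state[[id]] == 2L) return()
    state[[id]] <<- 1L
    for (ch in adj[[id]]) visit(ch)
    state[[id]] <<- 2L
  }
  for (id in ids) visit(id)
  found
}
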