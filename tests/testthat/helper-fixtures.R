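# Shared helpers: small deterministic objects built in code.

# Expression TSV on disk for IO tests.
writeTempExpression <- function(nGenes = 4, nTime = 6, seed = 1,
                                sep = "\t", path = tempfile(fileext = ".tsv")) {
  set.seed(seed)
  m <- matrix(round(runif(nGenes * nTime, 1, 100), 3), nGenes, nTime,
              dimnames = list(paste0("g", seq_len(nGenes)),
                              paste0("t", seq_len(nTime))))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  list(path = path, values = m)
}

# A hand-built directed network from an edge triple list.
makeNet <- function(edges, nodes = NULL) {
  ed <- do.call(rbind, lapply(edges, function(e)
    data.frame(source = e[[1]], target = e[[2]],
               weight = as.numeric(e[[3]]),
               delay = if (length(e) >= 4) as.integer(e[[4]]) else 1L,
               stringsAsFactors = FALSE)))
  if (is.null(nodes)) nodes <- unique(c(ed$source, ed$target))
  DirectedNetwork(nodes, ed)
}

edgeKeys <- function(net) {
  ed <- networkEdges(net)
  paste(ed$source, ed$target)
}
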