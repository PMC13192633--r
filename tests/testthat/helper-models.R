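tiny_master_for <- function(dec, hidden_dim = 32L, seed = 7L) {
  master_init(master_config(decoder_dim = dec$dim,
                            instr_vocab_size = dec$vocab_size,
                            num_layers = 2L, hidden_dim = hidden_dim,
                            num_heads = 4L),
              seed = seed)
}
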