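{
  "planted": {
    "cat1": ["tok0001", "tok0002", "tok0003"],
    "cat2": ["tok0004", "tok0005", "tok0006"],
    "cat3": ["tok0007", "tok0008", "tok0009"],
    "cat4": ["tok0010", "tok0011", "tok0012"]
  },
  "config": {
    "n_categories": 4,
    "reports_per_category": 10,
    "sentences_per_report": 3,
    "tokens_per_sentence": 6,
    "shared_vocab_size": 60,
    "signal_tokens_per_category": 3,
    "signal_boost": 20,
    "seed": 12061
  }
}
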