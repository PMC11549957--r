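#!/usr/bin/env python
"""Per-token conditional log-probabilities from a causal LM checkpoint.

Usage: causal_lm_logprobs.py <checkpoint> <max_sequence_length>
Reads the text on stdin; prints JSON {"logprobs": [...], "n": k}.
A BOS token is prepended so the first real token is conditionally scored;
the token sequence is truncated to max_sequence_length.
"""
import json
import sys


def main() -> int:
    checkpoint, max_len = sys.argv[1], int(sys.argv[2])
    text = sys.stdin.read()
    try:
        import torch
        from transformers import AutoModelForCausalLM, AutoTokenizer
    except ImportError as exc:  # surfaced to R as a scoring error
        print(json.dumps({"error": f"missing python dependency: {exc}"}))
        return 0
    tok = AutoTokenizer.from_pretrained(checkpoint)
    model = AutoModelForCausalLM.from_pretrained(checkpoint)
    model.eval()
    ids = tok(text, return_tensors="pt").input_ids[0][:max_len]
    if ids.numel() == 0:
        print(json.dumps({"error": "empty tokenization"}))
        return 0
    bos = tok.bos_token_id if tok.bos_token_id is not None else tok.eos_token_id
    inp = torch.cat([torch.tensor([bos]), ids]).unsqueeze(0)
    with torch.no_grad():
        logits = model(inp).logits[0]
    logprobs = torch.log_softmax(logits[:-1], dim=-1)
    lp = logprobs[range(ids.numel()), ids].tolist()
    print(json.dumps({"logprobs": lp, "n": len(lp)}))
    return 0


if __name__ == "__main__":
    sys.exit(main())
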