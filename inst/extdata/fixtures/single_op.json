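{
  "nodes": [
    {
      "label": "input_1_1",
      "type": "input",
      "passes": 1,
      "flags": [
        "is_input"
      ],
      "module_addresses": []
    },
    {
      "label": "tanh_1_2",
      "type": "tanh",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "output_1_3",
      "type": "output",
      "passes": 1,
      "flags": [
        "is_output"
      ],
      "module_addresses": []
    }
  ],
  "edges": [
    {
      "from": "input_1_1",
      "to": "tanh_1_2",
      "arg": "0"
    },
    {
      "from": "tanh_1_2",
      "to": "output_1_3",
      "arg": "0"
    }
  ],
  "name": "single_op"
}
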