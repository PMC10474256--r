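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
      "label": "rand_1_3",
      "type": "rand",
      "passes": 1,
      "flags": [
        "is_internally_generated"
      ],
      "module_addresses": []
    },
    {
      "label": "mul_1_4",
      "type": "mul",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "add_1_5",
      "type": "add",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "output_1_6",
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
      "from": "rand_1_3",
      "to": "mul_1_4",
      "arg": "0"
    },
    {
      "from": "tanh_1_2",
      "to": "add_1_5",
      "arg": "0"
    },
    {
      "from": "mul_1_4",
      "to": "add_1_5",
      "arg": "1"
    },
    {
      "from": "add_1_5",
      "to": "output_1_6",
      "arg": "0"
    }
  ],
  "name": "internal_rand"
}
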