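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
      "label": "mul_1_2",
      "type": "mul",
      "passes": 3,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "add_1_3",
      "type": "add",
      "passes": 3,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "tanh_1_4",
      "type": "tanh",
      "passes": 3,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "output_1_5",
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
      "to": "mul_1_2:1",
      "arg": "0"
    },
    {
      "from": "mul_1_2:1",
      "to": "add_1_3:1",
      "arg": "0"
    },
    {
      "from": "add_1_3:1",
      "to": "tanh_1_4:1",
      "arg": "0"
    },
    {
      "from": "tanh_1_4:1",
      "to": "mul_1_2:2",
      "arg": "0"
    },
    {
      "from": "mul_1_2:2",
      "to": "add_1_3:2",
      "arg": "0"
    },
    {
      "from": "add_1_3:2",
      "to": "tanh_1_4:2",
      "arg": "0"
    },
    {
      "from": "tanh_1_4:2",
      "to": "mul_1_2:3",
      "arg": "0"
    },
    {
      "from": "mul_1_2:3",
      "to": "add_1_3:3",
      "arg": "0"
    },
    {
      "from": "add_1_3:3",
      "to": "tanh_1_4:3",
      "arg": "0"
    },
    {
      "from": "tanh_1_4:3",
      "to": "output_1_5",
      "arg": "0"
    }
  ],
  "name": "xyz3"
}
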