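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
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "add_1_3",
      "type": "add",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "tanh_1_4",
      "type": "tanh",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "cos_1_5",
      "type": "cos",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "mul_2_6",
      "type": "mul",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "add_2_7",
      "type": "add",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "tanh_2_8",
      "type": "tanh",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "sin_1_9",
      "type": "sin",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "mul_3_10",
      "type": "mul",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "add_3_11",
      "type": "add",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "tanh_3_12",
      "type": "tanh",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "output_1_13",
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
      "to": "mul_1_2",
      "arg": "0"
    },
    {
      "from": "mul_1_2",
      "to": "add_1_3",
      "arg": "0"
    },
    {
      "from": "add_1_3",
      "to": "tanh_1_4",
      "arg": "0"
    },
    {
      "from": "tanh_1_4",
      "to": "cos_1_5",
      "arg": "0"
    },
    {
      "from": "cos_1_5",
      "to": "mul_2_6",
      "arg": "0"
    },
    {
      "from": "mul_2_6",
      "to": "add_2_7",
      "arg": "0"
    },
    {
      "from": "add_2_7",
      "to": "tanh_2_8",
      "arg": "0"
    },
    {
      "from": "tanh_2_8",
      "to": "sin_1_9",
      "arg": "0"
    },
    {
      "from": "sin_1_9",
      "to": "mul_3_10",
      "arg": "0"
    },
    {
      "from": "mul_3_10",
      "to": "add_3_11",
      "arg": "0"
    },
    {
      "from": "add_3_11",
      "to": "tanh_3_12",
      "arg": "0"
    },
    {
      "from": "tanh_3_12",
      "to": "output_1_13",
      "arg": "0"
    }
  ],
  "name": "xyzab"
}
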