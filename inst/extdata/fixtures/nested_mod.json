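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
      "label": "linear_1_2",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "stem.0"
      ]
    },
    {
      "label": "relu_1_3",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "stem.1",
        "stem"
      ]
    },
    {
      "label": "linear_2_4",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "block.b1.0"
      ]
    },
    {
      "label": "relu_2_5",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "block.b1.1",
        "block.b1"
      ]
    },
    {
      "label": "linear_3_6",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "block.b2.0"
      ]
    },
    {
      "label": "relu_3_7",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "block.b2.1",
        "block.b2"
      ]
    },
    {
      "label": "add_1_8",
      "type": "add",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "block"
      ]
    },
    {
      "label": "linear_4_9",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "head"
      ]
    },
    {
      "label": "output_1_10",
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
      "to": "linear_1_2",
      "arg": "0"
    },
    {
      "from": "linear_1_2",
      "to": "relu_1_3",
      "arg": "0"
    },
    {
      "from": "relu_1_3",
      "to": "linear_2_4",
      "arg": "0"
    },
    {
      "from": "linear_2_4",
      "to": "relu_2_5",
      "arg": "0"
    },
    {
      "from": "relu_1_3",
      "to": "linear_3_6",
      "arg": "0"
    },
    {
      "from": "linear_3_6",
      "to": "relu_3_7",
      "arg": "0"
    },
    {
      "from": "relu_2_5",
      "to": "add_1_8",
      "arg": "0"
    },
    {
      "from": "relu_3_7",
      "to": "add_1_8",
      "arg": "1"
    },
    {
      "from": "add_1_8",
      "to": "linear_4_9",
      "arg": "0"
    },
    {
      "from": "linear_4_9",
      "to": "output_1_10",
      "arg": "0"
    }
  ],
  "name": "nested_mod"
}
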