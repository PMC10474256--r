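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
      "label": "conv2d_1_2",
      "type": "conv2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.0"
      ]
    },
    {
      "label": "relu_1_3",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.1"
      ]
    },
    {
      "label": "maxpool2d_1_4",
      "type": "maxpool2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.2"
      ]
    },
    {
      "label": "conv2d_2_5",
      "type": "conv2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.3"
      ]
    },
    {
      "label": "relu_2_6",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.4"
      ]
    },
    {
      "label": "maxpool2d_2_7",
      "type": "maxpool2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.5"
      ]
    },
    {
      "label": "conv2d_3_8",
      "type": "conv2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.6"
      ]
    },
    {
      "label": "relu_3_9",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.7"
      ]
    },
    {
      "label": "conv2d_4_10",
      "type": "conv2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.8"
      ]
    },
    {
      "label": "relu_4_11",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.9"
      ]
    },
    {
      "label": "conv2d_5_12",
      "type": "conv2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.10"
      ]
    },
    {
      "label": "relu_5_13",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.11"
      ]
    },
    {
      "label": "maxpool2d_3_14",
      "type": "maxpool2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "features.12",
        "features"
      ]
    },
    {
      "label": "avgpool2d_1_15",
      "type": "avgpool2d",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "avgpool"
      ]
    },
    {
      "label": "flatten_1_16",
      "type": "flatten",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "dropout_1_17",
      "type": "dropout",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "classifier.0"
      ]
    },
    {
      "label": "linear_1_18",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "classifier.1"
      ]
    },
    {
      "label": "relu_6_19",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "classifier.2"
      ]
    },
    {
      "label": "dropout_2_20",
      "type": "dropout",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "classifier.3"
      ]
    },
    {
      "label": "linear_2_21",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "classifier.4"
      ]
    },
    {
      "label": "relu_7_22",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "classifier.5"
      ]
    },
    {
      "label": "linear_3_23",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "classifier.6",
        "classifier"
      ]
    },
    {
      "label": "output_1_24",
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
      "to": "conv2d_1_2",
      "arg": "0"
    },
    {
      "from": "conv2d_1_2",
      "to": "relu_1_3",
      "arg": "0"
    },
    {
      "from": "relu_1_3",
      "to": "maxpool2d_1_4",
      "arg": "0"
    },
    {
      "from": "maxpool2d_1_4",
      "to": "conv2d_2_5",
      "arg": "0"
    },
    {
      "from": "conv2d_2_5",
      "to": "relu_2_6",
      "arg": "0"
    },
    {
      "from": "relu_2_6",
      "to": "maxpool2d_2_7",
      "arg": "0"
    },
    {
      "from": "maxpool2d_2_7",
      "to": "conv2d_3_8",
      "arg": "0"
    },
    {
      "from": "conv2d_3_8",
      "to": "relu_3_9",
      "arg": "0"
    },
    {
      "from": "relu_3_9",
      "to": "conv2d_4_10",
      "arg": "0"
    },
    {
      "from": "conv2d_4_10",
      "to": "relu_4_11",
      "arg": "0"
    },
    {
      "from": "relu_4_11",
      "to": "conv2d_5_12",
      "arg": "0"
    },
    {
      "from": "conv2d_5_12",
      "to": "relu_5_13",
      "arg": "0"
    },
    {
      "from": "relu_5_13",
      "to": "maxpool2d_3_14",
      "arg": "0"
    },
    {
      "from": "maxpool2d_3_14",
      "to": "avgpool2d_1_15",
      "arg": "0"
    },
    {
      "from": "avgpool2d_1_15",
      "to": "flatten_1_16",
      "arg": "0"
    },
    {
      "from": "flatten_1_16",
      "to": "dropout_1_17",
      "arg": "0"
    },
    {
      "from": "dropout_1_17",
      "to": "linear_1_18",
      "arg": "0"
    },
    {
      "from": "linear_1_18",
      "to": "relu_6_19",
      "arg": "0"
    },
    {
      "from": "relu_6_19",
      "to": "dropout_2_20",
      "arg": "0"
    },
    {
      "from": "dropout_2_20",
      "to": "linear_2_21",
      "arg": "0"
    },
    {
      "from": "linear_2_21",
      "to": "relu_7_22",
      "arg": "0"
    },
    {
      "from": "relu_7_22",
      "to": "linear_3_23",
      "arg": "0"
    },
    {
      "from": "linear_3_23",
      "to": "output_1_24",
      "arg": "0"
    }
  ],
  "name": "alexnet"
}
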