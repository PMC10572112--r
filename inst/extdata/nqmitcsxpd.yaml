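# Dialect adapter for the PhysioNet nqmitcsxpd typing archive (one CSV per
# subject, millisecond clock). The archive does not ship a formal schema;
# this mapping follows its conventional column layout and should be verified
# against the downloaded files before use.
key_id: Key
press_time: Press
release_time: Release
subject_id: null
visit_index: null
time_unit: ms
delim: ","
file_glob: "*.csv"
subject_pattern: "^([A-Za-z0-9]+)_"
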