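{"schema_version":"1.0","boxes":[{"box_id":0,"vertices":[[10,54],[11,54],[11,55],[10,55]],"area":20000000000,"max_depth":80,"kind":"boundary","bedrock":0.05,"sand":0.6,"mud":0.35,"manmade":0},{"box_id":1,"vertices":[[12,55],[13,55],[13,56],[12,56]],"area":30000000000,"max_depth":25,"kind":"dynamic","bedrock":0.1,"sand":0.55,"mud":0.3,"manmade":0.05},{"box_id":2,"vertices":[[14,56],[15,56],[15,57],[14,57]],"area":40000000000,"max_depth":25,"kind":"dynamic","bedrock":0.05,"sand":0.5,"mud":0.45,"manmade":0},{"box_id":3,"vertices":[[16,57],[17,57],[17,58],[16,58]],"area":30000000000,"max_depth":30,"kind":"dynamic","bedrock":0.15,"sand":0.45,"mud":0.4,"manmade":0},{"box_id":4,"vertices":[[18,58],[19,58],[19,59],[18,59]],"area":30000000000,"max_depth":25,"kind":"dynamic","bedrock":0.05,"sand":0.55,"mud":0.4,"manmade":0},{"box_id":5,"vertices":[[20,59],[21,59],[21,60],[20,60]],"area":90000000000,"max_depth":80,"kind":"dynamic","bedrock":0,"sand":0.2,"mud":0.8,"manmade":0},{"box_id":6,"vertices":[[22,60],[23,60],[23,61],[22,61]],"area":110000000000,"max_depth":80,"kind":"dynamic","bedrock":0,"sand":0.15,"mud":0.85,"manmade":0},{"box_id":7,"vertices":[[24,61],[25,61],[25,62],[24,62]],"area":60000000000,"max_depth":60,"kind":"dynamic","bedrock":0,"sand":0.25,"mud":0.75,"manmade":0}],"faces":[{"face_id":0,"left_box":0,"right_box":1,"length":60000},{"face_id":1,"left_box":0,"right_box":5,"length":60000},{"face_id":2,"left_box":0,"right_box":6,"length":60000},{"face_id":3,"left_box":1,"right_box":2,"length":60000},{"face_id":4,"left_box":2,"right_box":3,"length":60000},{"face_id":5,"left_box":3,"right_box":4,"length":60000},{"face_id":6,"left_box":1,"right_box":5,"length":60000},{"face_id":7,"left_box":2,"right_box":5,"length":60000},{"face_id":8,"left_box":2,"right_box":6,"length":60000},{"face_id":9,"left_box":3,"right_box":6,"length":60000},{"face_id":10,"left_box":4,"right_box":7,"length":60000},{"face_id":11,"left_box":5,"right_box":6,"length":60000},{"face_id":12,"left_box":6,"right_box":7,"length":60000}],"layers":{"interface_depths":[10,30,80],"sediment_thickness":0.5}}
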