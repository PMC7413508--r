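phantom,insert,geometry,volume_ml,olinda,voxelmed,raydose
Cylindrical,Cylinder,cylinder,5640,3.3,2.8,3.0
Geometrical,To17a,torus,2.8,6.3,3.0,4.0
Geometrical,To17b,torus,2.8,0.8,0.4,0.5
Geometrical,To26,torus,9.7,15.4,9.0,10.7
Geometrical,E20,ellipsoid,4.1,21.1,16.1,17.6
Geometrical,E30,ellipsoid,14.8,23.0,20.7,20.9
Geometrical,E38,ellipsoid,28.5,24.1,23.9,23.7
Geometrical,P38,pear,29.2,2.5,2.0,2.1
Geometrical,P39a,pear,30.1,2.5,2.0,2.1
Geometrical,P39b,pear,31.2,2.1,2.0,2.0
Geometrical,Tu38a,tube,28.6,2.5,2.0,1.9
Geometrical,Tu38b,tube,28.8,2.4,2.0,2.0
Anthropomorphic,Lesion,sphere,2.0,102.3,91.3,97.9
Anthropomorphic,Pancreas,organ,92,13.6,11.9,12.2
Anthropomorphic,Kidneys,organ,284,12.9,11.4,11.8
Anthropomorphic,Spleen,organ,156,22.0,19.6,20.3
Anthropomorphic,Liver,organ,1470,10.4,9.3,9.8
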